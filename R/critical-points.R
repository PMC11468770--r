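#' Extract branching- and terminal-point candidates
#'
#' Prunes tiny terminal branches (fewer than `min_nodes` records, see
#' [prune_short_terminal_branches()]) and then emits every branching point
#' (non-soma nodes with two children, plus the soma if it has two or more)
#' and every tip as a verification candidate. Coordinates are scaled by
#' `resolution_scale` per axis into the image frame.
#'
#' @param tree A [neuron_tree()].
#' @param resolution_scale Per-axis multiplicative factor (length 1 or 3).
#' @param min_nodes Pruning threshold (default 6).
#' @return A tibble with columns `x`, `y`, `z`, `kind`
#'   (`"branching"`/`"terminal"`), `source_node`.
#' @export
extract_candidates <- function(tree, resolution_scale = 1, min_nodes = 6) {
  sc <- rep_len(as.double(resolution_scale), 3)
  tr <- prune_short_terminal_branches(tree, min_nodes = min_nodes)
  n <- nrow(tr)
  if (n == 0) {
    return(tibble::tibble(x = double(), y = double(), z = double(),
                          kind = character(), source_node = integer()))
  }
  kids <- children_index(tr)
  nk <- lengths(kids)
  roots <- root_rows(tr)
  is_root <- logical(n)
  is_root[roots] <- TRUE
  br <- which((nk >= 2 & !is_root) | (is_root & nk >= 2))
  tip <- which(nk == 0 & !is_root)
  tibble::tibble(
    x = tr$x[c(br, tip)] * sc[1],
    y = tr$y[c(br, tip)] * sc[2],
    z = tr$z[c(br, tip)] * sc[3],
    kind = c(rep("branching", length(br)), rep("terminal", length(tip))),
    source_node = tr$id[c(br, tip)]
  )
}

#' Build an image/mask patch pair around a candidate
#'
#' Crops a `size`-cubed image patch centred on the candidate (zero-padded
#' where it overhangs the volume) and rasterises the local reconstruction
#' into a binary mask of the same dimensions: a mask voxel is 1 when its
#' centre lies within the local node radius (at least 1 voxel) of any tree
#' edge intersecting the patch.
#'
#' @param volume An [image_volume()].
#' @param tree A [neuron_tree()] in whole-frame voxel coordinates.
#' @param center 0-based whole-frame voxel coordinate.
#' @param size Patch side length (default 32).
#' @return A `patch_pair`: list with `image_patch`, `mask_patch` (both
#'   `size^3` arrays) and `center`.
#' @export
make_patch_pair <- function(volume, tree, center, size = 32) {
  cr <- pad_crop(volume, round(center), size)
  mask <- rasterize_tree_mask(tree, origin = cr$origin, dims = rep(size, 3))
  structure(
    list(image_patch = cr$data, mask_patch = mask, center = as.double(center),
         origin = cr$origin),
    class = "patch_pair"
  )
}

# binary raster of all tree edges into a grid with 0-based `origin` and
# dimensions `dims`; dilation radius per node = max(radius, min_radius)
rasterize_tree_mask <- function(tree, origin, dims, min_radius = 1) {
  mask <- array(FALSE, dim = dims)
  if (nrow(tree) == 0) return(mask)
  prow <- match(tree$parent, tree$id)
  has <- which(!is.na(prow) & tree$parent != -1L)
  hi_bound <- origin + dims - 1
  for (i in has) {
    p <- prow[i]
    a <- c(tree$x[i], tree$y[i], tree$z[i])
    b <- c(tree$x[p], tree$y[p], tree$z[p])
    r <- max(tree$radius[i], tree$radius[p], min_radius)
    lo <- pmax(floor(pmin(a, b) - r), origin)
    hi <- pmin(ceiling(pmax(a, b) + r), hi_bound)
    if (any(lo > hi)) next
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    g <- expand.grid(x = xs, y = ys, z = zs)
    d <- point_segment_distance(as.matrix(g), a, b)
    sel <- d <= r
    if (!any(sel)) next
    idx <- cbind(g$x[sel], g$y[sel], g$z[sel]) -
      matrix(origin, sum(sel), 3, byrow = TRUE) + 1
    mask[idx] <- TRUE
  }
  mask
}

# distance from each row of pts to segment a-b
point_segment_distance <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2 + (pts[, 3] - a[3])^2))
  }
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2] +
          (pts[, 3] - a[3]) * ab[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((pts[, 1] - (a[1] + t * ab[1]))^2 +
         (pts[, 2] - (a[2] + t * ab[2]))^2 +
         (pts[, 3] - (a[3] + t * ab[3]))^2)
}

# connected components (6-neighbourhood) of a logical 3-D array via igraph;
# returns an integer array: 0 background, 1..k component labels
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  fg <- which(mask)
  if (length(fg) == 0) return(lab)
  pos <- arrayInd(fg, d)
  lin <- function(x, y, z) (z - 1) * d[1] * d[2] + (y - 1) * d[1] + x
  idx_of <- integer(prod(d))
  idx_of[fg] <- seq_along(fg)
  edges <- list()
  for (axis in 1:3) {
    shift <- c(0, 0, 0)
    shift[axis] <- 1
    nx <- pos[, 1] + shift[1]; ny <- pos[, 2] + shift[2]; nz <- pos[, 3] + shift[3]
    ok <- nx <= d[1] & ny <= d[2] & nz <= d[3]
    if (!any(ok)) next
    nb <- lin(nx[ok], ny[ok], nz[ok])
    okfg <- idx_of[nb] > 0
    if (!any(okfg)) next
    edges[[axis]] <- cbind(which(ok)[okfg], idx_of[nb[okfg]])
  }
  em <- do.call(rbind, edges)
  if (is.null(em) || nrow(em) == 0) {
    lab[fg] <- seq_along(fg)
    return(lab)
  }
  g <- igraph::graph_from_edgelist(
    matrix(as.numeric(em), ncol = 2), directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[fg] <- as.integer(comp)
  lab
}

# Otsu threshold of a patch on its native intensity scale
patch_otsu <- function(patch) {
  v <- as.vector(patch)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  if (requireNamespace("EBImage", quietly = TRUE)) {
    # EBImage only needs the intensity histogram, so a flat matrix works
    img <- EBImage::Image(matrix((v - rng[1]) / diff(rng), ncol = 1))
    thr <- EBImage::otsu(img, range = c(0, 1))
    return(rng[1] + thr * diff(rng))
  }
  # fallback: exhaustive between-class variance maximisation on 256 bins
  h <- tabulate(pmin(floor((v - rng[1]) / diff(rng) * 255), 255) + 1, 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma[!is.finite(sigma)] <- 0
  rng[1] + (which.max(sigma) - 1) / 255 * diff(rng)
}

# number of disjoint clusters of foreground voxels on the patch boundary,
# restricted to the component(s) passing near the patch centre
boundary_exit_count <- function(patch) {
  # Otsu bisects the noise when foreground is sparse; floor the threshold at
  # a robust background estimate so near-empty patches stay background
  thr <- max(patch_otsu(patch),
             stats::median(patch) + 3 * stats::mad(patch))
  fg <- patch > thr
  if (!any(fg)) return(0L)
  lab <- label_components_3d(fg)
  d <- dim(patch)
  ctr <- ceiling(d / 2)
  # component containing (or nearest to) the centre
  w <- 2
  sub <- lab[max(1, ctr[1] - w):min(d[1], ctr[1] + w),
             max(1, ctr[2] - w):min(d[2], ctr[2] + w),
             max(1, ctr[3] - w):min(d[3], ctr[3] + w)]
  comp_ids <- setdiff(unique(as.vector(sub)), 0L)
  if (length(comp_ids) == 0) {
    fgpos <- arrayInd(which(fg), d)
    dist <- sqrt((fgpos[, 1] - ctr[1])^2 + (fgpos[, 2] - ctr[2])^2 +
                   (fgpos[, 3] - ctr[3])^2)
    comp_ids <- lab[which(fg)[which.min(dist)]]
  }
  keep <- array(lab %in% comp_ids, dim = d)
  on_boundary <- array(FALSE, dim = d)
  on_boundary[1, , ] <- TRUE; on_boundary[d[1], , ] <- TRUE
  on_boundary[, 1, ] <- TRUE; on_boundary[, d[2], ] <- TRUE
  on_boundary[, , 1] <- TRUE; on_boundary[, , d[3]] <- TRUE
  exits <- keep & on_boundary
  if (!any(exits)) return(0L)
  # cluster the exit voxels with a generous adjacency so one neurite exit
  # crossing an edge of the cube counts once
  pos <- arrayInd(which(exits), d)
  ne <- nrow(pos)
  if (ne == 1) return(1L)
  adj <- matrix(FALSE, ne, ne)
  for (i in seq_len(ne - 1)) {
    dd <- abs(pos[(i + 1):ne, , drop = FALSE] -
                matrix(pos[i, ], ne - i, 3, byrow = TRUE))
    close <- rowSums(dd <= 2) == 3
    adj[i, (i + 1):ne][close] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj | t(adj), mode = "undirected")
  igraph::components(g)$no
}

#' Reference heuristic critical-point classifier
#'
#' A non-learned verifier usable wherever a trained model is unavailable:
#' the patch is thresholded at its Otsu level, the foreground component
#' around the centre is traced to the patch boundary, and the boundary
#' crossings are clustered. A genuine branching point shows at least three
#' disjoint exits; a genuine terminal shows at most one (the side the
#' neurite entered from). Returns a probability-like score in \{0, 1\}.
#'
#' @param pair A `patch_pair`.
#' @param kind `"branching"` or `"terminal"`.
#' @return A probability in \[0, 1\].
#' @export
heuristic_classifier <- function(pair, kind) {
  exits <- boundary_exit_count(pair$image_patch)
  if (kind == "branching") {
    as.double(exits >= 3)
  } else {
    as.double(exits <= 1)
  }
}

#' Verify critical-point candidates with a pluggable classifier
#'
#' Applies a classifier satisfying the verifier contract — a function
#' `(patch_pair, kind) -> probability in [0, 1]` — to each patch pair and
#' labels a candidate positive when the probability is at least 0.5. Trained
#' models (e.g. convolutional networks for branching/terminal verification)
#' plug in through the same contract; the package ships
#' [heuristic_classifier()] as the reference implementation.
#'
#' @param pairs List of `patch_pair` objects.
#' @param kinds Character vector, `"branching"`/`"terminal"` per pair.
#' @param classifier A function `(pair, kind) -> probability`.
#' @return A tibble with columns `kind`, `probability`, `label` (logical).
#' @export
verify_candidates <- function(pairs, kinds, classifier = heuristic_classifier) {
  stopifnot(length(pairs) == length(kinds))
  prob <- vapply(seq_along(pairs), function(i) {
    p <- classifier(pairs[[i]], kinds[i])
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      rlang::abort("classifier contract violation: probability outside [0, 1]")
    }
    as.double(p)
  }, double(1))
  tibble::tibble(kind = kinds, probability = prob, label = prob >= 0.5)
}

#' Evaluate verifier predictions against an expert reconstruction
#'
#' A branching candidate's true class is positive when a branching point of
#' the expert tree lies within `match_radius`; a terminal candidate's true
#' class is positive when an expert terminal lies within `match_radius` (a
#' nearby continuation does not count). Precision, recall and accuracy come
#' from [confusion_metrics()].
#'
#' @param candidates Tibble from [extract_candidates()] (columns `x`, `y`,
#'   `z`, `kind`).
#' @param predicted Logical vector of predicted labels per candidate.
#' @param expert_tree The expert-validated [neuron_tree()] in the same frame.
#' @param match_radius Voxels (default 4).
#' @return A one-row tibble: `tp`, `tn`, `fp`, `fn`, `precision`, `recall`,
#'   `accuracy`.
#' @export
evaluate_verifier <- function(candidates, predicted, expert_tree,
                              match_radius = 4) {
  stopifnot(nrow(candidates) == length(predicted))
  exp_cand <- extract_candidates(expert_tree, min_nodes = 1)
  truth <- vapply(seq_len(nrow(candidates)), function(i) {
    pool <- exp_cand[exp_cand$kind == candidates$kind[i], , drop = FALSE]
    if (nrow(pool) == 0) return(FALSE)
    d <- sqrt((pool$x - candidates$x[i])^2 + (pool$y - candidates$y[i])^2 +
                (pool$z - candidates$z[i])^2)
    any(d <= match_radius)
  }, logical(1))
  tp <- sum(predicted & truth)
  tn <- sum(!predicted & !truth)
  fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth)
  cm <- suppressWarnings(confusion_metrics(tp, tn, fp, fn))
  tibble::tibble(tp = tp, tn = tn, fp = fp, fn = fn,
                 precision = cm$precision, recall = cm$recall,
                 accuracy = cm$accuracy)
}
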