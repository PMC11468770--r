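#' Signal-complexity map of a volume
#'
#' The reconstruction (with its radii) defines a foreground mask; the volume
#' is decomposed into cubes (default 20 voxels per side) and each cube's
#' signal complexity is the mean foreground intensity divided by the mean
#' background intensity. Cubes without foreground score 0. The raw map is
#' min-max rescaled into the 8-bit range so it can be browsed as an image.
#'
#' @param volume An [image_volume()].
#' @param tree A [neuron_tree()] in the volume's voxel frame, with radii.
#' @param cube Cube side length in voxels (default 20).
#' @return An [image_volume()] of the cube-grid shape (8-bit); the raw
#'   complexity values are attached as attribute `"raw"`.
#' @export
signal_complexity_map <- function(volume, tree, cube = 20) {
  d <- dim(volume$data)
  mask <- rasterize_tree_mask(tree, origin = volume$origin, dims = d)
  if (!any(mask)) {
    rlang::warn("no foreground voxels: signal-complexity map is all zero")
  }
  grid <- partition_blocks(d, block = cube)
  gshape <- c(length(unique(grid$x0)), length(unique(grid$y0)),
              length(unique(grid$z0)))
  raw <- array(0, dim = gshape)
  for (i in seq_len(nrow(grid))) {
    xs <- (grid$x0[i] + 1):grid$x1[i]
    ys <- (grid$y0[i] + 1):grid$y1[i]
    zs <- (grid$z0[i] + 1):grid$z1[i]
    sub <- volume$data[xs, ys, zs, drop = FALSE]
    m <- mask[xs, ys, zs, drop = FALSE]
    gi <- c(grid$x0[i] / cube, grid$y0[i] / cube, grid$z0[i] / cube) + 1
    if (!any(m) || all(m)) next # no foreground (or no background) -> 0
    raw[gi[1], gi[2], gi[3]] <- mean(sub[m]) / mean(sub[!m])
  }
  rng <- range(raw)
  scaled <- if (diff(rng) == 0) {
    array(0, dim = gshape)
  } else {
    round((raw - rng[1]) / diff(rng) * 255)
  }
  out <- image_volume(scaled, voxel_size = volume$voxel_size * cube,
                      origin = volume$origin / cube, bit_depth = 8)
  attr(out, "raw") <- raw
  out
}

#' Local structural complexity (point-centred Sholl analysis)
#'
#' Extends Sholl analysis by treating every node — not just the soma — as a
#' centre: for each probe radius, the number of tree edges crossing the
#' sphere of that radius around the node is counted (an edge crosses when
#' its endpoints straddle the sphere). The per-node score is the sum of
#' crossing counts over all probe radii.
#'
#' @param tree A [neuron_tree()], resampled finely relative to the smallest
#'   probe radius.
#' @param radii Numeric vector of probe radii in the tree's units.
#' @param per_radius Return the long per-radius table instead of summed
#'   scores.
#' @return A tibble `id`, `score` (or `id`, `radius`, `crossings` when
#'   `per_radius = TRUE`).
#' @export
local_structural_complexity <- function(tree, radii, per_radius = FALSE) {
  n <- nrow(tree)
  if (n == 0) {
    return(if (per_radius) {
      tibble::tibble(id = integer(), radius = double(), crossings = integer())
    } else {
      tibble::tibble(id = integer(), score = integer())
    })
  }
  pts <- cbind(tree$x, tree$y, tree$z)
  prow <- match(tree$parent, tree$id)
  has <- which(!is.na(prow) & tree$parent != -1L)
  counts <- matrix(0L, nrow = n, ncol = length(radii))
  if (length(has) > 0) {
    for (ci in seq_len(n)) {
      dc <- sqrt((pts[, 1] - pts[ci, 1])^2 + (pts[, 2] - pts[ci, 2])^2 +
                   (pts[, 3] - pts[ci, 3])^2)
      d1 <- dc[has]
      d2 <- dc[prow[has]]
      for (ri in seq_along(radii)) {
        r <- radii[ri]
        # an endpoint exactly on the sphere counts with the inside
        counts[ci, ri] <- sum(xor(d1 > r, d2 > r))
      }
    }
  }
  if (per_radius) {
    tibble::tibble(
      id = rep(tree$id, times = length(radii)),
      radius = rep(radii, each = n),
      crossings = as.integer(counts)
    )
  } else {
    tibble::tibble(id = tree$id, score = as.integer(rowSums(counts)))
  }
}

#' User attention per node
#'
#' Counts, for every node, the number of distinct users whose annotation
#' events (add/delete/confirm, located by the geometry of the segment they
#' touch) fall inside an axis-aligned box of side `box` centred on the node
#' (closed on the lower face, open on the upper).
#'
#' @param tree A [neuron_tree()].
#' @param log An [edit_log()] whose geometry shares the tree's units.
#' @param box Box side length (default 20, micrometers).
#' @return A tibble `id`, `attention`.
#' @export
user_attention <- function(tree, log, box = 20) {
  ev <- log_events(log)
  geom_by_seg <- list()
  pts <- list()
  for (i in seq_len(nrow(ev))) {
    if (ev$action[i] == "add" && !is.null(ev$geometry[[i]])) {
      geom_by_seg[[ev$segment_id[i]]] <- ev$geometry[[i]]
    }
    g <- geom_by_seg[[ev$segment_id[i]]]
    if (is.null(g)) next
    pts[[length(pts) + 1]] <- tibble::tibble(
      user = ev$user[i], x = g$x, y = g$y, z = g$z
    )
  }
  if (length(pts) == 0) {
    return(tibble::tibble(id = tree$id, attention = 0L))
  }
  p <- dplyr::bind_rows(pts)
  half <- box / 2
  att <- vapply(seq_len(nrow(tree)), function(i) {
    inb <- p$x >= tree$x[i] - half & p$x < tree$x[i] + half &
      p$y >= tree$y[i] - half & p$y < tree$y[i] + half &
      p$z >= tree$z[i] - half & p$z < tree$z[i] + half
    length(unique(p$user[inb]))
  }, integer(1))
  tibble::tibble(id = tree$id, attention = att)
}

# ---- non-negative matrix factorisation -------------------------------------

# Deterministic rank-k NMF: NNDSVD-style initialisation from the truncated
# SVD followed by multiplicative Frobenius updates (Lee & Seung).
nmf_decompose <- function(V, rank = 3, n_iter = 200, eps = 1e-9) {
  stopifnot(all(V >= 0), rank >= 1, ncol(V) >= rank)
  sv <- svd(V, nu = rank, nv = rank)
  W <- matrix(0, nrow(V), rank)
  H <- matrix(0, rank, ncol(V))
  for (k in seq_len(rank)) {
    u <- sv$u[, k]
    v <- sv$v[, k]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npos >= nneg) {
      W[, k] <- sqrt(sv$d[k] * npos) * up / max(sqrt(sum(up^2)), eps)
      H[k, ] <- sqrt(sv$d[k] * npos) * vp / max(sqrt(sum(vp^2)), eps)
    } else {
      W[, k] <- sqrt(sv$d[k] * nneg) * un / max(sqrt(sum(un^2)), eps)
      H[k, ] <- sqrt(sv$d[k] * nneg) * vn / max(sqrt(sum(vn^2)), eps)
    }
  }
  mean_v <- mean(V)
  W[W <= 0] <- mean_v / 100
  H[H <= 0] <- mean_v / 100
  for (it in seq_len(n_iter)) {
    H <- H * (crossprod(W, V) / (crossprod(W) %*% H + eps))
    W <- W * (V %*% t(H) / (W %*% tcrossprod(H) + eps))
  }
  list(W = W, H = H)
}

#' NMF-based image-quality report
#'
#' Every `slab` consecutive z-slices are averaged and flattened into the
#' columns of a non-negative matrix, which is factorised with a
#' deterministic rank-`rank` NMF (default 3 components). The component
#' whose spatial loading varies least (smallest coefficient of variation)
#' is taken as the background; the signal is the original matrix minus the
#' background reconstruction, clipped at zero. To limit cross-talk, only
#' background values below their 99th percentile and signal values above
#' their 90th percentile enter the statistics:
#' `signal_median`, `signal_rsd` (= sd(signal) / median(signal)) and
#' `contrast` (absolute difference of the filtered medians;
#' `literal_contrast = TRUE` gives the signed background-minus-signal
#' value).
#'
#' @param volume An [image_volume()] with at least `slab` z-slices.
#' @param slab Slices averaged per slab (default 10).
#' @param rank Number of NMF components (default 3).
#' @param literal_contrast Use the signed convention.
#' @return A `quality_report` list with `signal_median`, `signal_rsd`,
#'   `contrast`, `n_components`.
#' @export
nmf_image_quality <- function(volume, slab = 10, rank = 3,
                              literal_contrast = FALSE) {
  d <- dim(volume$data)
  if (d[3] < slab) rlang::abort("volume has fewer z-slices than one slab")
  n_slabs <- d[3] %/% slab
  if (n_slabs < rank) {
    rlang::abort(sprintf(
      "need at least %d slabs (%d z-slices) for a rank-%d factorisation",
      rank, rank * slab, rank
    ))
  }
  V <- matrix(0, d[1] * d[2], n_slabs)
  for (s in seq_len(n_slabs)) {
    zs <- ((s - 1) * slab + 1):(s * slab)
    V[, s] <- as.vector(apply(volume$data[, , zs, drop = FALSE], c(1, 2), mean))
  }
  if (stats::sd(V) == 0) {
    rlang::abort("constant volume: NMF decomposition is degenerate")
  }
  dec <- nmf_decompose(V, rank = rank)
  cv <- vapply(seq_len(rank), function(k) {
    w <- dec$W[, k]
    if (mean(w) <= 0) Inf else stats::sd(w) / mean(w)
  }, double(1))
  bg_k <- which.min(cv)
  B <- dec$W[, bg_k, drop = FALSE] %*% dec$H[bg_k, , drop = FALSE]
  S <- pmax(V - B, 0)
  S_f <- S[S >= stats::quantile(S, 0.9)]
  B_f <- B[B <= stats::quantile(B, 0.99)]
  sig_med <- stats::median(S_f)
  if (sig_med == 0) {
    rlang::abort("degenerate decomposition: filtered signal median is zero")
  }
  contrast <- stats::median(B_f) - sig_med
  structure(
    list(
      signal_median = sig_med,
      signal_rsd = stats::sd(S_f) / sig_med,
      contrast = if (literal_contrast) contrast else abs(contrast),
      n_components = as.integer(rank)
    ),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(
    "# quality_report: signal median = %.2f, signal rsd = %.4f, contrast = %.2f (%d NMF components)\n",
    x$signal_median, x$signal_rsd, x$contrast, x$n_components
  ))
  invisible(x)
}

#' @rdname tidy.match_report
#' @export
glance.quality_report <- function(x, ...) {
  tibble::tibble(
    signal_median = x$signal_median, signal_rsd = x$signal_rsd,
    contrast = x$contrast, n_components = x$n_components
  )
}
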