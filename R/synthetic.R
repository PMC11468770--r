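#' Specification of a synthetic neuron phantom
#'
#' Bundles every parameter of the synthetic ground truth: the volume
#' geometry, the random tree (branch count, lengths, shaft radii), the soma
#' ball(s), the varicosity (bouton) swellings, and the imaging model
#' (intensities, additive Gaussian noise, bright blob artifacts emulating
#' vessel fluorescence and dye leakage). All generators are pure functions
#' of the spec, seed included.
#'
#' The default voxel size (0.46, 0.46, 2.0) micrometers reproduces the
#' anisotropic block geometry typical of whole-brain light-microscopy data
#' (a 256-voxel side spanning 117.76 um laterally and 512 um axially).
#' Geometry is generated in voxel coordinates. Default artifact blobs have
#' radius 3 voxels — bright specks below the soma-detection distance band,
#' stressing the band filter rather than duplicating somas.
#'
#' @param volume_shape Volume shape in voxels.
#' @param voxel_size Micrometers per voxel.
#' @param n_branches Number of neurite branch segments (0 for a bare soma).
#' @param branch_length_range Branch length range, voxels.
#' @param shaft_radius_range Neurite radius range, voxels.
#' @param soma_radius Soma radius in voxels (scalar or range; extra somas
#'   sample from it).
#' @param n_somas Total soma count (the tree root plus isolated extras).
#' @param bouton List: `count`, `radius_ratio` (>= 1), `spacing` (voxels).
#' @param intensity List: `shaft`, `soma`, `background`, `noise_sd`,
#'   `n_artifacts`, `artifact_radius`.
#' @param bit_depth 8 or 16.
#' @param seed Integer seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(volume_shape = c(256, 256, 256),
                         voxel_size = c(0.46, 0.46, 2.0),
                         n_branches = 8,
                         branch_length_range = c(30, 80),
                         shaft_radius_range = c(1.5, 2.5),
                         soma_radius = 10,
                         n_somas = 1,
                         bouton = list(count = 10, radius_ratio = 1.8, spacing = 12),
                         intensity = list(shaft = 300, soma = 500,
                                          background = 50, noise_sd = 50,
                                          n_artifacts = 2, artifact_radius = 3),
                         bit_depth = 16,
                         seed = 1) {
  stopifnot(
    length(volume_shape) == 3, all(volume_shape >= 8),
    all(branch_length_range > 0), all(shaft_radius_range > 0),
    all(soma_radius > 0), bouton$radius_ratio >= 1,
    bit_depth %in% c(8, 16), n_somas >= 1
  )
  defaults_int <- list(shaft = 300, soma = 500, background = 50, noise_sd = 50,
                       n_artifacts = 2, artifact_radius = 3)
  for (nm in names(defaults_int)) {
    if (is.null(intensity[[nm]])) intensity[[nm]] <- defaults_int[[nm]]
  }
  defaults_b <- list(count = 10, radius_ratio = 1.8, spacing = 12)
  for (nm in names(defaults_b)) {
    if (is.null(bouton[[nm]])) bouton[[nm]] <- defaults_b[[nm]]
  }
  structure(
    list(
      volume_shape = as.integer(volume_shape), voxel_size = as.double(voxel_size),
      n_branches = as.integer(n_branches),
      branch_length_range = as.double(branch_length_range),
      shaft_radius_range = as.double(shaft_radius_range),
      soma_radius = as.double(soma_radius), n_somas = as.integer(n_somas),
      bouton = bouton, intensity = intensity,
      bit_depth = as.integer(bit_depth), seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# sample uniformly in [a, b] given a scalar-or-range parameter
sample_range <- function(r, n = 1) {
  if (length(r) == 1) rep(r, n) else stats::runif(n, r[1], r[2])
}

#' Generate a random ground-truth neuron tree
#'
#' Grows a quasi-binary tree from a soma at the volume centre: branches are
#' polylines with lengths, radii and branching angles sampled within the
#' spec's ranges, constrained to stay inside the volume with a safety
#' margin. Neurites are typed as axon (2) so bouton profiling applies.
#' Deterministic per seed.
#'
#' @param spec A [phantom_spec()].
#' @return A [neuron_tree()] in voxel coordinates.
#' @export
make_tree <- function(spec) {
  shape <- spec$volume_shape
  margin <- max(max(spec$soma_radius), 4) + 2
  center <- (shape - 1) / 2
  with_preserved_seed(spec$seed, {
    soma_r <- sample_range(spec$soma_radius, 1)[1]
    rows <- list(tibble::tibble(
      id = 1L, type = 1L, x = center[1], y = center[2], z = center[3],
      radius = soma_r, parent = -1L
    ))
    next_id <- 2L
    # open attachment points: node id, position, outgoing direction, #children
    atts <- list(list(id = 1L, pos = center, dir = NULL, kids = 0L, is_soma = TRUE))
    n_made <- 0L
    guard <- 0L
    while (n_made < spec$n_branches && guard < 200L * max(spec$n_branches, 1L)) {
      guard <- guard + 1L
      ai <- sample.int(length(atts), 1)
      at <- atts[[ai]]
      max_kids <- if (at$is_soma) 4L else 2L
      if (at$kids >= max_kids) next
      L <- stats::runif(1, spec$branch_length_range[1], spec$branch_length_range[2])
      r <- stats::runif(1, spec$shaft_radius_range[1], spec$shaft_radius_range[2])
      ok <- FALSE
      for (try in 1:25) {
        dir <- if (is.null(at$dir)) {
          v <- stats::rnorm(3)
          v / sqrt(sum(v^2))
        } else {
          v <- at$dir + stats::rnorm(3, sd = 0.45)
          v / sqrt(sum(v^2))
        }
        endp <- at$pos + dir * L
        if (all(endp > margin) && all(endp < shape - 1 - margin)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) next
      n_nodes <- max(3L, ceiling(L / 3))
      t <- seq_len(n_nodes) / n_nodes
      jig <- matrix(stats::rnorm(3 * n_nodes, sd = 0.5), ncol = 3)
      jig[n_nodes, ] <- 0
      pos <- matrix(at$pos, n_nodes, 3, byrow = TRUE) + outer(t * L, dir) + jig
      pos <- pmin(pmax(pos, margin), matrix(shape - 1 - margin, n_nodes, 3, byrow = TRUE))
      ids <- next_id:(next_id + n_nodes - 1L)
      next_id <- next_id + n_nodes
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = as.integer(ids), type = 2L,
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        radius = rep(r, n_nodes),
        parent = as.integer(c(at$id, ids[-n_nodes]))
      )
      atts[[ai]]$kids <- at$kids + 1L
      atts[[length(atts) + 1]] <- list(
        id = ids[n_nodes], pos = pos[n_nodes, ], dir = dir, kids = 0L,
        is_soma = FALSE
      )
      n_made <- n_made + 1L
    }
    if (n_made < spec$n_branches) {
      rlang::abort("phantom tree does not fit the volume; enlarge it or shorten branches")
    }
    neuron_tree(dplyr::bind_rows(rows), unit = "voxel",
                voxel_size = spec$voxel_size)
  })
}

# add a Gaussian ball (peak `peak`, scale sigma) into `vol` by max-combine
draw_ball <- function(vol, center, radius, peak, hard = TRUE) {
  d <- dim(vol)
  pad <- ceiling(radius + 4)
  lo <- pmax(floor(center - pad), 0)
  hi <- pmin(ceiling(center + pad), d - 1)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  dist <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2)
  val <- if (hard) {
    ifelse(dist <= radius, peak, peak * exp(-(dist - radius)^2 / 2))
  } else {
    peak * exp(-dist^2 / (2 * (radius / 2)^2))
  }
  idx <- cbind(g$x, g$y, g$z) + 1
  vol[idx] <- pmax(vol[idx], val)
  vol
}

#' Render a phantom volume from a ground-truth tree
#'
#' Draws Gaussian-profile tubes along every edge (peak at the shaft
#' intensity, cross-section sigma = radius / 2, light-microscopy style),
#' hard soma balls, varicosity swellings at regularly spaced axon sites
#' (recorded as truth bouton markers), optional bright blob artifacts, and
#' additive Gaussian background noise, clipped to the bit depth.
#'
#' @param tree A [neuron_tree()] from [make_tree()] (voxel coordinates).
#' @param spec The [phantom_spec()] used to build the tree.
#' @return A list with `volume` (an [image_volume()]) and `truth` (a tibble
#'   of soma and bouton markers with columns `x`, `y`, `z`, `radius`,
#'   `label`).
#' @export
render_volume <- function(tree, spec) {
  shape <- spec$volume_shape
  inten <- spec$intensity
  with_preserved_seed(spec$seed + 1L, {
    vol <- array(0, dim = shape)
    truth <- list()

    # neurite tubes
    prow <- match(tree$parent, tree$id)
    has <- which(!is.na(prow) & tree$parent != -1L)
    for (i in has) {
      p <- prow[i]
      a <- c(tree$x[i], tree$y[i], tree$z[i])
      b <- c(tree$x[p], tree$y[p], tree$z[p])
      if (tree$type[p] == 1L) { # shorten edges into the soma ball
        dirv <- b - a
        dl <- sqrt(sum(dirv^2))
        if (dl > tree$radius[p]) b <- b - dirv / dl * (tree$radius[p] * 0.5)
      }
      r <- max(tree$radius[i], 0.8)
      sigma <- r / 2
      pad <- ceiling(3 * sigma + 1)
      lo <- pmax(floor(pmin(a, b) - pad), 0)
      hi <- pmin(ceiling(pmax(a, b) + pad), shape - 1)
      if (any(lo > hi)) next
      xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
      g <- expand.grid(x = xs, y = ys, z = zs)
      dist <- point_segment_distance(as.matrix(g), a, b)
      val <- inten$shaft * exp(-dist^2 / (2 * sigma^2))
      idx <- cbind(g$x, g$y, g$z) + 1
      vol[idx] <- pmax(vol[idx], val)
    }

    # somas: the tree root plus isolated extras
    roots <- root_rows(tree)
    centers <- list()
    for (r0 in roots) {
      ctr <- c(tree$x[r0], tree$y[r0], tree$z[r0])
      vol <- draw_ball(vol, ctr, tree$radius[r0], inten$soma)
      centers[[length(centers) + 1]] <- c(ctr, tree$radius[r0])
      truth[[length(truth) + 1]] <- tibble::tibble(
        x = ctr[1], y = ctr[2], z = ctr[3], radius = tree$radius[r0],
        label = "soma"
      )
    }
    n_extra <- spec$n_somas - length(roots)
    tries <- 0L
    while (n_extra > 0 && tries < 500L) {
      tries <- tries + 1L
      rr <- sample_range(spec$soma_radius, 1)[1]
      pos <- stats::runif(3, rr + 4, shape - 1 - rr - 4)
      sep_ok <- all(vapply(centers, function(cc) {
        sqrt(sum((cc[1:3] - pos)^2)) > (cc[4] + rr + 10)
      }, logical(1)))
      if (!sep_ok) next
      vol <- draw_ball(vol, pos, rr, inten$soma)
      centers[[length(centers) + 1]] <- c(pos, rr)
      truth[[length(truth) + 1]] <- tibble::tibble(
        x = pos[1], y = pos[2], z = pos[3], radius = rr, label = "soma"
      )
      n_extra <- n_extra - 1L
    }

    # varicosities along the axon, spaced along arc length
    if (spec$bouton$count > 0 && any(tree$type == 2L)) {
      ax <- tibble::as_tibble(tree)[tree$type == 2L, , drop = FALSE]
      ax$parent[!(ax$parent %in% ax$id)] <- -1L
      rs <- resample_tree(tree_like(tree, ax), 1)
      # keep sites away from the soma and from each other
      ctr0 <- c(tree$x[roots[1]], tree$y[roots[1]], tree$z[roots[1]])
      dsoma <- sqrt((rs$x - ctr0[1])^2 + (rs$y - ctr0[2])^2 + (rs$z - ctr0[3])^2)
      # varicosities sit along shafts: keep sites away from the soma and
      # from topological endpoints (tips, bifurcations), where a shaft
      # profile is undefined
      nk_rs <- n_children(rs)
      ep <- which(nk_rs != 1L)
      dep <- rep(Inf, nrow(rs))
      if (length(ep) > 0) {
        dep <- apply(cbind(rs$x, rs$y, rs$z), 1, function(p) {
          min(sqrt((rs$x[ep] - p[1])^2 + (rs$y[ep] - p[2])^2 +
                     (rs$z[ep] - p[3])^2))
        })
      }
      pool <- which(dsoma > tree$radius[roots[1]] + 8 & dep > 5)
      pool <- pool[sample.int(length(pool))]
      sites <- integer(0)
      for (cand in pool) {
        if (length(sites) >= spec$bouton$count) break
        if (length(sites) > 0) {
          dd <- sqrt((rs$x[sites] - rs$x[cand])^2 +
                       (rs$y[sites] - rs$y[cand])^2 +
                       (rs$z[sites] - rs$z[cand])^2)
          if (any(dd < spec$bouton$spacing)) next
        }
        sites <- c(sites, cand)
      }
      for (s in sites) {
        rb <- spec$bouton$radius_ratio * rs$radius[s]
        ctr <- c(rs$x[s], rs$y[s], rs$z[s])
        vol <- draw_ball(vol, ctr, rb, min(inten$shaft * 1.3, 2^spec$bit_depth - 1),
                         hard = FALSE)
        truth[[length(truth) + 1]] <- tibble::tibble(
          x = ctr[1], y = ctr[2], z = ctr[3], radius = rb, label = "bouton"
        )
      }
    }

    # bright blob artifacts (vessel fluorescence / dye leakage stand-ins)
    if (inten$n_artifacts > 0) {
      for (k in seq_len(inten$n_artifacts)) {
        rr <- inten$artifact_radius
        pos <- stats::runif(3, rr + 2, shape - 1 - rr - 2)
        vol <- draw_ball(vol, pos, rr, inten$soma)
      }
    }

    maxval <- 2^spec$bit_depth - 1
    vol <- vol + inten$background +
      array(stats::rnorm(prod(shape), sd = inten$noise_sd), dim = shape)
    vol <- round(pmin(pmax(vol, 0), maxval))
    list(
      volume = image_volume(vol, voxel_size = spec$voxel_size,
                            origin = c(0, 0, 0), bit_depth = spec$bit_depth),
      truth = if (length(truth)) dplyr::bind_rows(truth) else
        tibble::tibble(x = double(), y = double(), z = double(),
                       radius = double(), label = character())
    )
  })
}

#' Voronoi region labels
#'
#' Partitions a voxel grid into `n_regions` regions by nearest seeded site
#' (Euclidean in voxel space); labels are 1..n_regions. Deterministic per
#' seed.
#'
#' @param shape Volume shape in voxels.
#' @param n_regions Number of regions (>= 1).
#' @param seed Integer seed.
#' @return An [image_volume()] of integer labels.
#' @export
make_region_labels <- function(shape, n_regions, seed = 1) {
  stopifnot(n_regions >= 1, length(shape) == 3)
  with_preserved_seed(seed, {
    sites <- matrix(stats::runif(3 * n_regions, 0, rep(shape - 1, each = n_regions)),
                    ncol = 3)
    lab <- array(0L, dim = shape)
    xs <- 0:(shape[1] - 1)
    ys <- 0:(shape[2] - 1)
    gx <- matrix(rep(xs, times = shape[2]), ncol = shape[2])
    gy <- matrix(rep(ys, each = shape[1]), ncol = shape[2])
    for (z in 0:(shape[3] - 1)) {
      best_d <- NULL
      best_l <- NULL
      for (k in seq_len(n_regions)) {
        d <- (gx - sites[k, 1])^2 + (gy - sites[k, 2])^2 + (z - sites[k, 3])^2
        if (is.null(best_d)) {
          best_d <- d
          best_l <- array(k, dim = dim(d))
        } else {
          upd <- d < best_d
          best_d[upd] <- d[upd]
          best_l[upd] <- k
        }
      }
      lab[, , z + 1] <- best_l
    }
    image_volume(lab, voxel_size = c(1, 1, 1), origin = c(0, 0, 0),
                 bit_depth = if (n_regions < 256) 8 else 16)
  })
}
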