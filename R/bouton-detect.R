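# trilinear interpolation of a 3-D array at 0-based fractional coordinates
trilinear <- function(data, pts) {
  d <- dim(data)
  px <- pmin(pmax(pts[, 1], 0), d[1] - 1)
  py <- pmin(pmax(pts[, 2], 0), d[2] - 1)
  pz <- pmin(pmax(pts[, 3], 0), d[3] - 1)
  x0 <- pmin(floor(px), d[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(py), d[2] - 2); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(pz), d[3] - 2); z0 <- pmax(z0, 0)
  if (d[1] == 1) x0 <- rep(0, length(px))
  if (d[2] == 1) y0 <- rep(0, length(py))
  if (d[3] == 1) z0 <- rep(0, length(pz))
  fx <- px - x0; fy <- py - y0; fz <- pz - z0
  at <- function(ix, iy, iz) {
    data[cbind(pmin(ix, d[1] - 1) + 1, pmin(iy, d[2] - 1) + 1,
               pmin(iz, d[3] - 1) + 1)]
  }
  c000 <- at(x0, y0, z0); c100 <- at(x0 + 1, y0, z0)
  c010 <- at(x0, y0 + 1, z0); c110 <- at(x0 + 1, y0 + 1, z0)
  c001 <- at(x0, y0, z0 + 1); c101 <- at(x0 + 1, y0, z0 + 1)
  c011 <- at(x0, y0 + 1, z0 + 1); c111 <- at(x0 + 1, y0 + 1, z0 + 1)
  (c000 * (1 - fx) + c100 * fx) * (1 - fy) * (1 - fz) +
    (c010 * (1 - fx) + c110 * fx) * fy * (1 - fz) +
    (c001 * (1 - fx) + c101 * fx) * (1 - fy) * fz +
    (c011 * (1 - fx) + c111 * fx) * fy * fz
}

# separable 3^3 box smoothing (running mean of width 3 per axis)
box_smooth3 <- function(a) {
  d <- dim(a)
  smooth_axis <- function(x, axis) {
    n <- d[axis]
    if (n < 2) return(x)
    idx_lo <- c(1, seq_len(n - 1))
    idx_hi <- c(seq_len(n - 1) + 1, n)
    if (axis == 1) {
      (x[idx_lo, , , drop = FALSE] + x + x[idx_hi, , , drop = FALSE]) / 3
    } else if (axis == 2) {
      (x[, idx_lo, , drop = FALSE] + x + x[, idx_hi, , drop = FALSE]) / 3
    } else {
      (x[, , idx_lo, drop = FALSE] + x + x[, , idx_hi, drop = FALSE]) / 3
    }
  }
  smooth_axis(smooth_axis(smooth_axis(a, 1), 2), 3)
}

# per-block min-max rescale of a 16-bit volume to the 8-bit range
rescale_8bit <- function(volume) {
  v <- volume$data
  if (volume$bit_depth == 8) return(v)
  rng <- range(v)
  if (diff(rng) == 0) return(array(0, dim = dim(v)))
  (v - rng[1]) / diff(rng) * 255
}

#' Estimate the local neurite radius at a point
#'
#' Returns the largest integer radius `r` (up to `r_max`) such that at least
#' `frac` of the voxels on the sphere surface of radius `r` around the point
#' exceed the background threshold; 0 if the point itself is at or below
#' background. Voxels outside the volume count as background. Raising the
#' threshold can never increase the estimate.
#'
#' @param volume An [image_volume()].
#' @param point 0-based whole-frame voxel coordinate.
#' @param background_threshold Intensity above which a voxel is foreground
#'   (same scale as the stored data).
#' @param r_max Largest radius probed (voxels, default 15).
#' @param frac Required foreground fraction on the surface (default 0.85).
#' @return Integer radius in voxels.
#' @export
estimate_radius <- function(volume, point, background_threshold, r_max = 15,
                            frac = 0.85) {
  d <- dim(volume$data)
  p <- round(point - volume$origin) # 0-based local
  if (any(p < 0) || any(p > d - 1)) rlang::abort("`point` lies outside the volume")
  if (volume$data[p[1] + 1, p[2] + 1, p[3] + 1] <= background_threshold) {
    return(0L)
  }
  best <- 0L
  for (r in seq_len(r_max)) {
    off <- sphere_surface_offsets(r)
    sx <- p[1] + off[, 1]; sy <- p[2] + off[, 2]; sz <- p[3] + off[, 3]
    inside <- sx >= 0 & sx < d[1] & sy >= 0 & sy < d[2] & sz >= 0 & sz < d[3]
    vals <- rep(-Inf, nrow(off))
    if (any(inside)) {
      vals[inside] <- volume$data[cbind(sx[inside] + 1, sy[inside] + 1,
                                        sz[inside] + 1)]
    }
    if (mean(vals > background_threshold) >= frac) best <- r
  }
  best
}

# integer offsets on the sphere shell of radius r (cached per radius)
sphere_surface_offsets <- local({
  cache <- list()
  function(r) {
    key <- as.character(r)
    if (!is.null(cache[[key]])) return(cache[[key]])
    s <- seq(-r, r)
    g <- expand.grid(x = s, y = s, z = s)
    dist <- sqrt(g$x^2 + g$y^2 + g$z^2)
    out <- as.matrix(g[dist >= r - 0.5 & dist < r + 0.5, , drop = FALSE])
    cache[[key]] <<- out
    out
  }
})

#' Intensity and radius profiles along axonal shafts
#'
#' The axon-typed part of the tree (structure type 2) is resampled at `step`
#' and, at every resampled node, the 8-bit image intensity (trilinear
#' interpolation; 16-bit volumes are min-max rescaled per block) and the
#' local radius estimate ([estimate_radius()]) are recorded. Profiles are
#' kept per branch, so peaks never span a bifurcation.
#'
#' @param volume An [image_volume()] covering the axon.
#' @param tree A [neuron_tree()] in voxel coordinates with axon nodes.
#' @param step Resampling step in voxels (default 1).
#' @param background_threshold Foreground threshold on the 8-bit scale for
#'   the radius estimate. The default (`NULL`) adapts per profile point:
#'   block median plus a quarter of the local centre intensity above it,
#'   which tracks the brightness variation along unevenly labelled axons.
#'   Radii are estimated on a 3-voxel box-smoothed copy of the volume to
#'   suppress voxel noise; intensities are sampled from the raw volume.
#' @param r_max Largest radius probed.
#' @return An `axon_profile` tibble with columns `branch`, `arc_pos`, `x`,
#'   `y`, `z`, `intensity`, `radius`, `node_ref`.
#' @export
profile_axon <- function(volume, tree, step = 1, background_threshold = NULL,
                         r_max = 15) {
  axon <- tibble::as_tibble(tree)[tree$type == 2L, , drop = FALSE]
  if (nrow(axon) == 0) rlang::abort("tree contains no axon-typed (2) nodes")
  axon$parent[!(axon$parent %in% axon$id)] <- -1L
  ax_tree <- tree_like(tree, axon)
  rs <- resample_tree(ax_tree, step)

  d <- dim(volume$data)
  loc <- cbind(rs$x, rs$y, rs$z) - matrix(volume$origin, nrow(rs), 3, byrow = TRUE)
  bad <- which(loc[, 1] < 0 | loc[, 1] > d[1] - 1 |
                 loc[, 2] < 0 | loc[, 2] > d[2] - 1 |
                 loc[, 3] < 0 | loc[, 3] > d[3] - 1)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "axon nodes outside the volume: ",
      paste(utils::head(rs$id[bad], 10), collapse = ", "),
      if (length(bad) > 10) " ..." else ""
    ))
  }
  img8 <- rescale_8bit(volume)
  smooth8 <- box_smooth3(img8)
  vol8s <- image_volume(smooth8, voxel_size = volume$voxel_size,
                        origin = volume$origin, bit_depth = 8)
  intensity <- trilinear(img8, loc)
  center_s <- trilinear(smooth8, loc)
  med <- stats::median(smooth8)
  thr_at <- if (is.null(background_threshold)) {
    pmax(med + 0.25 * (center_s - med), med + 5)
  } else {
    rep(background_threshold, nrow(rs))
  }
  radius <- vapply(seq_len(nrow(rs)), function(i) {
    as.double(estimate_radius(vol8s, c(rs$x[i], rs$y[i], rs$z[i]),
                              thr_at[i], r_max = r_max))
  }, double(1))

  # branch ids + arc positions along each unbranched path of the resampled axon
  paths <- branch_paths(rs)
  out <- vector("list", length(paths))
  for (b in seq_along(paths)) {
    path <- paths[[b]]
    seg <- sqrt(diff(rs$x[path])^2 + diff(rs$y[path])^2 + diff(rs$z[path])^2)
    out[[b]] <- tibble::tibble(
      branch = b,
      arc_pos = c(0, cumsum(seg)),
      x = rs$x[path], y = rs$y[path], z = rs$z[path],
      intensity = intensity[path],
      radius = radius[path],
      node_ref = rs$id[path]
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "step") <- step
  attr(res, "background_threshold") <- background_threshold
  class(res) <- c("axon_profile", class(res))
  res
}

# moving average of odd width with shrinking windows at the ends
moving_average <- function(v, width = 3) {
  n <- length(v)
  if (n == 0) return(v)
  half <- width %/% 2
  vapply(seq_len(n), function(i) {
    mean(v[max(1, i - half):min(n, i + half)])
  }, double(1))
}

# indices of interior local maxima of v; a flat plateau bounded by smaller
# values on both sides counts once, at its centre
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (k in seq_along(r$values)) {
    if (starts[k] == 1L || ends[k] == n) next
    if (r$values[k] > v[starts[k] - 1L] && r$values[k] > v[ends[k] + 1L]) {
      out <- c(out, as.integer(floor((starts[k] + ends[k]) / 2)))
    }
  }
  out
}

#' Detect putative boutons from an axon profile
#'
#' Boutons (presynaptic varicosities) appear as overlapping peaks in the
#' intensity and radius profiles along an axonal shaft. Candidates are
#' intensity peaks (after moving-average smoothing) that have a radius peak
#' within `overlap_window` nodes. Heuristic filters then require the
#' candidate radius to be at least `ratio` (default 1.5) times the median
#' radius of the surrounding nodes and the 8-bit intensity to exceed
#' `intensity_min` (default 120). Finally duplicate candidates closer than
#' `dedupe_radius` voxels (Euclidean, default 5) are discarded, keeping the
#' higher-intensity one.
#'
#' @param profile An `axon_profile` from [profile_axon()].
#' @param ratio Radius ratio threshold over the surrounding median.
#' @param intensity_min 8-bit intensity threshold (exclusive).
#' @param dedupe_radius Minimum separation between reported boutons.
#' @param overlap_window Peak-overlap window in resampled nodes (default 3).
#' @param surround Surrounding-node window per side for the median radius
#'   (default 10), excluding the candidate and its peak plateau.
#' @param smooth_width Moving-average width (default 3).
#' @return A tibble of bouton annotations.
#' @export
detect_boutons <- function(profile, ratio = 1.5, intensity_min = 120,
                           dedupe_radius = 5, overlap_window = 3,
                           surround = 10, smooth_width = 3) {
  if (nrow(profile) == 0) return(point_annotation(label = "bouton"))
  cands <- list()
  for (b in unique(profile$branch)) {
    pr <- profile[profile$branch == b, , drop = FALSE]
    n <- nrow(pr)
    si <- moving_average(pr$intensity, smooth_width)
    sr <- moving_average(pr$radius, smooth_width)
    ip <- local_maxima(si)
    rp <- local_maxima(sr)
    if (length(ip) == 0 || length(rp) == 0) next
    for (i in ip) {
      if (min(abs(rp - i)) > overlap_window) next
      lo <- max(1, i - surround)
      hi <- min(n, i + surround)
      # exclude the candidate's contiguous radius plateau (plus the overlap
      # window) so the swelling does not inflate its own baseline
      pl_lo <- i
      while (pl_lo > lo && pr$radius[pl_lo - 1] >= pr$radius[i]) pl_lo <- pl_lo - 1
      pl_hi <- i
      while (pl_hi < hi && pr$radius[pl_hi + 1] >= pr$radius[i]) pl_hi <- pl_hi + 1
      surr <- setdiff(lo:hi, (min(pl_lo, i - overlap_window)):(max(pl_hi, i + overlap_window)))
      if (length(surr) == 0) next
      med <- stats::median(pr$radius[surr])
      if (pr$intensity[i] <= intensity_min) next
      if (med > 0 && pr$radius[i] < ratio * med) next
      if (med == 0 && pr$radius[i] <= 0) next
      cands[[length(cands) + 1]] <- tibble::tibble(
        x = pr$x[i], y = pr$y[i], z = pr$z[i],
        radius = pr$radius[i], score = pr$intensity[i]
      )
    }
  }
  if (length(cands) == 0) return(point_annotation(label = "bouton"))
  cand <- dplyr::bind_rows(cands)
  # deduplicate: greedy by descending intensity, drop anything closer than
  # dedupe_radius to a kept bouton
  ord <- order(-cand$score, cand$x, cand$y, cand$z)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (any(keep)) {
      d <- sqrt((cand$x[keep] - cand$x[i])^2 + (cand$y[keep] - cand$y[i])^2 +
                  (cand$z[keep] - cand$z[i])^2)
      if (any(d < dedupe_radius)) next
    }
    keep[i] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  point_annotation(cand$x, cand$y, cand$z, radius = cand$radius,
                   score = cand$score, label = "bouton")
}

#' Score detections against ground truth
#'
#' Greedy one-to-one matching by ascending distance within `match_radius`:
#' each truth point is matched to at most one detection and vice versa.
#' Precision and recall come from [confusion_metrics()] with the
#' true-negative count fixed at 0, and F1 is their harmonic mean.
#'
#' @param detected,truth Tibbles with columns `x`, `y`, `z`.
#' @param match_radius Maximum match distance in voxels.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`.
#' @export
evaluate_boutons <- function(detected, truth, match_radius = 5) {
  nd <- nrow(detected)
  nt <- nrow(truth)
  tp <- 0L
  if (nd > 0 && nt > 0) {
    dmat <- outer(seq_len(nd), seq_len(nt), function(i, j) {
      sqrt((detected$x[i] - truth$x[j])^2 + (detected$y[i] - truth$y[j])^2 +
             (detected$z[i] - truth$z[j])^2)
    })
    pairs <- which(dmat <= match_radius, arr.ind = TRUE)
    if (nrow(pairs) > 0) {
      pairs <- pairs[order(dmat[pairs]), , drop = FALSE]
      used_d <- logical(nd)
      used_t <- logical(nt)
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        if (!used_d[i] && !used_t[j]) {
          used_d[i] <- TRUE
          used_t[j] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  fp <- nd - tp
  fn <- nt - tp
  cm <- suppressWarnings(confusion_metrics(tp, 0, fp, fn))
  f1 <- if (is.finite(cm$precision) && is.finite(cm$recall) &&
            (cm$precision + cm$recall) > 0) {
    2 * cm$precision * cm$recall / (cm$precision + cm$recall)
  } else {
    0
  }
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 precision = cm$precision, recall = cm$recall, f1 = f1)
}
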