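#' Point annotations
#'
#' Detections and markers (somas, boutons, critical points) are plain
#' tibbles with columns `x`, `y`, `z` (0-based whole-frame voxel
#' coordinates), `radius` (voxels), `score` (detector confidence; for somas,
#' the distance-transform value), `label` and optional `user`.
#'
#' @param x,y,z Voxel coordinates.
#' @param radius Radii in voxels.
#' @param score Detector confidence.
#' @param label One of `"soma_candidate"`, `"soma_confirmed"`, `"bouton"`,
#'   `"branch_point"`, `"terminal_point"`.
#' @param user Optional annotator id.
#' @return A tibble.
#' @export
point_annotation <- function(x = double(), y = double(), z = double(),
                             radius = 0, score = NA_real_,
                             label = "soma_candidate", user = NA_character_) {
  n <- length(x)
  tibble::tibble(
    x = as.double(x), y = as.double(y), z = as.double(z),
    radius = rep_len(as.double(radius), n),
    score = rep_len(as.double(score), n),
    label = rep_len(as.character(label), n),
    user = rep_len(as.character(user), n)
  )
}

#' Read / write marker CSV files
#'
#' The marker format is a one-header-line CSV with columns
#' `x,y,z,radius,score,label` (and optionally `user`).
#'
#' @param markers A tibble of annotations (see [point_annotation()]).
#' @param path CSV file path.
#' @return `read_markers()` returns a tibble; `write_markers()` returns
#'   `path` invisibly.
#' @export
write_markers <- function(markers, path) {
  utils::write.csv(as.data.frame(markers), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Detect soma candidates in an image block
#'
#' The automatic soma-candidate pipeline for one image block:
#' \enumerate{
#'   \item blocks whose maximal intensity is below `min_max` (250 for 16-bit
#'     input) are discarded outright — for 8-bit input this filter is skipped
#'     with a warning;
#'   \item the block is z-score normalised, clipped at ±3 standard deviations
#'     and mapped affinely to the unsigned 8-bit range;
#'   \item the 8-bit block is binarised at its 99th intensity percentile
#'     (linear interpolation over the full histogram);
#'   \item the foreground is distance transformed (exact Euclidean by
#'     default; `transform = "geodesic"` switches to a gray-weighted
#'     geodesic transform);
#'   \item voxels whose transform value falls in `band` (default 5–30
#'     voxels) become candidates, scored by the transform value, with the
#'     candidate radius set to that value;
#'   \item redundant candidates are removed by [non_max_suppress()].
#' }
#'
#' @param block An [image_volume()]; its `origin` shifts the reported
#'   coordinates into the whole-volume frame.
#' @param band Numeric length-2, the accepted distance-transform range.
#' @param min_max Minimal block maximum intensity for 16-bit input.
#' @param nms_radius Suppression radius in voxels.
#' @param percentile Binarisation percentile (default 0.99).
#' @param transform Distance-transform strategy.
#' @return A tibble of soma-candidate annotations.
#' @export
detect_soma_candidates <- function(block, band = c(5, 30), min_max = 250,
                                   nms_radius = 15, percentile = 0.99,
                                   transform = c("euclidean", "geodesic")) {
  transform <- match.arg(transform)
  if (!is_image_volume(block) || length(block$data) == 0) {
    rlang::abort("`block` must be a non-empty image_volume")
  }
  v <- block$data
  if (block$bit_depth == 16) {
    if (max(v) < min_max) return(point_annotation())
  } else {
    rlang::warn("8-bit block: skipping the 16-bit maximal-intensity filter")
  }
  mu <- mean(v)
  sdv <- stats::sd(as.vector(v))
  if (sdv == 0) return(point_annotation())
  z <- (v - mu) / sdv
  img8 <- (pmin(pmax(z, -3), 3) + 3) / 6 * 255
  thr <- stats::quantile(img8, percentile, names = FALSE)
  fg <- img8 >= thr # >= so the top percentile survives even when it clips at 255
  if (!any(fg)) return(point_annotation())
  dt <- if (transform == "euclidean") {
    .edt3d(as.vector(fg), dim(v))
  } else {
    .gwdt3d(as.vector(img8) / 255, as.vector(fg), dim(v))
  }
  sel <- which(dt >= band[1] & dt <= band[2])
  if (length(sel) == 0) return(point_annotation())
  coords <- arrayInd(sel, dim(v)) - 1 # 0-based local
  cand <- point_annotation(
    x = coords[, 1] + block$origin[1],
    y = coords[, 2] + block$origin[2],
    z = coords[, 3] + block$origin[3],
    radius = dt[sel], score = dt[sel], label = "soma_candidate"
  )
  kept <- non_max_suppress(cand, radius = nms_radius)
  # suppression must also scale with the detected radius: a candidate lying
  # inside a stronger candidate's ball (transform value = distance to
  # background, i.e. blob radius) is the same object
  keep <- logical(nrow(kept))
  for (i in seq_len(nrow(kept))) {
    if (any(keep)) {
      d <- sqrt((kept$x[keep] - kept$x[i])^2 + (kept$y[keep] - kept$y[i])^2 +
                  (kept$z[keep] - kept$z[i])^2)
      if (any(d <= pmax(nms_radius, kept$radius[keep]))) next
    }
    keep[i] <- TRUE
  }
  kept[keep, , drop = FALSE]
}

#' Non-maximum suppression of point detections
#'
#' Greedy suppression by descending score: a candidate is kept if and only
#' if no already-kept candidate lies within `radius` of it. Score ties are
#' broken by lexicographic (x, y, z) order, so the result does not depend on
#' the input ordering.
#'
#' @param candidates A tibble with columns `x`, `y`, `z`, `score`.
#' @param radius Suppression radius (same units as the coordinates).
#' @return The kept subset, in decreasing score order.
#' @export
non_max_suppress <- function(candidates, radius) {
  n <- nrow(candidates)
  if (n <= 1) return(candidates)
  ord <- order(-candidates$score, candidates$x, candidates$y, candidates$z)
  cx <- candidates$x[ord]
  cy <- candidates$y[ord]
  cz <- candidates$z[ord]
  alive <- rep(TRUE, n)
  keep <- logical(n)
  r2 <- radius^2
  repeat {
    nxt <- which(alive)[1]
    if (is.na(nxt)) break
    keep[nxt] <- TRUE
    d2 <- (cx - cx[nxt])^2 + (cy - cy[nxt])^2 + (cz - cz[nxt])^2
    alive <- alive & d2 > r2
  }
  candidates[ord[keep], , drop = FALSE]
}
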