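#' Harmonic-mean reconstruction accuracy
#'
#' The accuracy of a reconstruction against a reference is the harmonic mean
#' \eqn{2 R_c R_m / (R_c + R_m)} of the correctly-traced ratio \eqn{R_c}
#' (fraction of the test reconstruction's length lying on the reference) and
#' the recovered ratio \eqn{R_m} (fraction of the reference length that was
#' traced, i.e. one minus the missing fraction). Defined as 0 when both
#' ratios are 0.
#'
#' @param Rc,Rm Ratios in \[0, 1\] (vectorised).
#' @return Numeric accuracy in \[0, 1\].
#' @examples
#' accuracy_statistic(0.8, 0.9)
#' @export
accuracy_statistic <- function(Rc, Rm) {
  if (any(!is.finite(Rc)) || any(!is.finite(Rm)) ||
      any(Rc < 0 | Rc > 1) || any(Rm < 0 | Rm > 1)) {
    rlang::abort("`Rc` and `Rm` must lie in [0, 1]")
  }
  out <- ifelse(Rc + Rm == 0, 0, 2 * Rc * Rm / (Rc + Rm))
  as.double(out)
}

#' Precision, recall and accuracy from a confusion matrix
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return A one-row tibble with columns `precision`, `recall`, `accuracy`.
#'   A zero denominator yields `NaN` with a warning.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    rlang::abort("confusion counts must be non-negative")
  }
  div <- function(num, den, what) {
    if (den == 0) {
      rlang::warn(paste0(what, " undefined: zero denominator"))
      return(NaN)
    }
    num / den
  }
  tibble::tibble(
    precision = div(tp, tp + fp, "precision"),
    recall = div(tp, tp + fn, "recall"),
    accuracy = div(tp + tn, tp + tn + fp + fn, "accuracy")
  )
}

# length of a voxel edge in the tree's coordinate units
voxel_step <- function(tree) {
  if (tree_unit(tree) == "voxel") 1 else mean(tree_voxel_size(tree))
}

# exact nearest neighbour from each row of `query` to rows of `ref`;
# returns list(index, distance); ties broken by lower ref index
nearest_points <- function(query, ref) {
  query <- as.matrix(query)
  ref <- as.matrix(ref)
  if (nrow(ref) == 0) {
    return(list(index = rep(NA_integer_, nrow(query)),
                distance = rep(NA_real_, nrow(query))))
  }
  rng <- apply(ref, 2, function(v) diff(range(v)))
  cell <- max(rng) / max(nrow(ref)^(1 / 3), 1)
  if (!is.finite(cell) || cell <= 0) {
    # degenerate reference (single point or coincident points): any cell works
    cell <- 1
  }
  .grid_nn(query, ref, cell)
}

#' Length-based matching between two reconstructions
#'
#' Both trees are resampled to a common fine step (at most half the distance
#' threshold, and no coarser than one voxel), then every resampled edge of
#' the test tree is counted as matched when its midpoint lies within
#' `dist_threshold` of the reference, and vice versa. The matched fractions
#' give \eqn{R_c} (test side) and \eqn{R_m} (reference side), combined into
#' the harmonic-mean accuracy by [accuracy_statistic()].
#'
#' Two empty trees agree perfectly (accuracy 1); one empty tree against a
#' non-empty one scores 0.
#'
#' @param test,ref [neuron_tree()]s in a common coordinate frame.
#' @param dist_threshold Match distance in the trees' coordinate units
#'   (default: two voxel lengths).
#' @return A `match_report` object; see [glance.match_report()].
#' @export
match_length <- function(test, ref, dist_threshold = 2 * voxel_step(test)) {
  stopifnot(dist_threshold > 0)
  new_report <- function(mt, ut, mr, ur) {
    tt <- mt + ut
    tr <- mr + ur
    Rc <- if (tt > 0) mt / tt else NA_real_
    Rm <- if (tr > 0) mr / tr else NA_real_
    acc <- if (tt == 0 && tr == 0) {
      1
    } else if (tt == 0 || tr == 0) {
      0
    } else {
      accuracy_statistic(Rc, Rm)
    }
    structure(
      list(
        matched_length_test = mt, unmatched_length_test = ut,
        matched_length_ref = mr, unmatched_length_ref = ur,
        Rc = Rc, Rm = Rm, accuracy = acc,
        distance_threshold = dist_threshold
      ),
      class = "match_report"
    )
  }
  if (nrow(test) == 0 || nrow(ref) == 0) {
    return(new_report(0, total_length(test), 0, total_length(ref)))
  }
  step <- min(voxel_step(test), dist_threshold / 2)
  ts <- resample_tree(test, step)
  rs <- resample_tree(ref, step)
  side <- function(a, b) {
    prow <- match(a$parent, a$id)
    has <- !is.na(prow) & a$parent != -1L
    if (!any(has)) return(c(0, 0))
    mid <- cbind(
      (a$x[has] + a$x[prow[has]]) / 2,
      (a$y[has] + a$y[prow[has]]) / 2,
      (a$z[has] + a$z[prow[has]]) / 2
    )
    len <- edge_lengths(a)[has]
    nn <- nearest_points(mid, cbind(b$x, b$y, b$z))
    matched <- nn$distance <= dist_threshold
    c(sum(len[matched]), sum(len[!matched]))
  }
  t_side <- side(ts, rs)
  r_side <- side(rs, ts)
  new_report(t_side[1], t_side[2], r_side[1], r_side[2])
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "# match_report (threshold %.3g): Rc = %.4f, Rm = %.4f, accuracy = %.4f\n",
    x$distance_threshold, x$Rc, x$Rm, x$accuracy
  ))
  invisible(x)
}

#' Tidiers for comparison reports
#'
#' `tidy()` returns the per-side matched/unmatched length decomposition;
#' `glance()` returns the one-row summary with `Rc`, `Rm` and `accuracy`.
#'
#' @param x A `match_report` from [match_length()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.match_report <- function(x, ...) {
  tibble::tibble(
    side = c("test", "reference"),
    matched_length = c(x$matched_length_test, x$matched_length_ref),
    unmatched_length = c(x$unmatched_length_test, x$unmatched_length_ref),
    total_length = matched_length + unmatched_length
  )
}

#' @rdname tidy.match_report
#' @export
glance.match_report <- function(x, ...) {
  tibble::tibble(
    Rc = x$Rc, Rm = x$Rm, accuracy = x$accuracy,
    distance_threshold = x$distance_threshold
  )
}

#' Bidirectional consistency between two reconstructions of one neuron
#'
#' For every node of `a` the nearest node of `b` is found, and vice versa;
#' the mean of the two directional mean distances is the bidirectional
#' distance, and the fraction of all pooled node-wise nearest distances below
#' the threshold (default two voxels) is the consistency. Symmetric in its
#' arguments.
#'
#' @param a,b Non-empty [neuron_tree()]s in a common frame.
#' @param threshold_voxels Distance threshold in voxels (default 2).
#' @return A `consistency_report` list with `mean_bidirectional_distance`,
#'   `fraction_within` and `threshold_voxels`; see [glance.consistency_report()].
#' @export
consistency <- function(a, b, threshold_voxels = 2) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    rlang::abort("consistency is undefined for empty reconstructions")
  }
  thr <- threshold_voxels * voxel_step(a)
  pa <- cbind(a$x, a$y, a$z)
  pb <- cbind(b$x, b$y, b$z)
  dab <- nearest_points(pa, pb)$distance
  dba <- nearest_points(pb, pa)$distance
  structure(
    list(
      mean_bidirectional_distance = (mean(dab) + mean(dba)) / 2,
      fraction_within = mean(c(dab, dba) < thr),
      threshold_voxels = threshold_voxels
    ),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "# consistency_report: mean bidirectional distance = %.4f, fraction within %g voxels = %.4f\n",
    x$mean_bidirectional_distance, x$threshold_voxels, x$fraction_within
  ))
  invisible(x)
}

#' @rdname tidy.match_report
#' @export
glance.consistency_report <- function(x, ...) {
  tibble::tibble(
    mean_bidirectional_distance = x$mean_bidirectional_distance,
    fraction_within = x$fraction_within,
    threshold_voxels = x$threshold_voxels
  )
}
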