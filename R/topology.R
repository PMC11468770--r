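#' Topological height of every node
#'
#' Terminal nodes (tips) have topological height (TH) 1; a branching point's
#' TH is one plus the highest TH among its children. Pass-through (unary)
#' nodes inherit their child's TH unchanged, which keeps TH a branch-level
#' quantity invariant under resampling. The root therefore carries the tree
#' maximum. TH measures the corrective effort a mistake at a node implies:
#' the higher the node, the more downstream structure depends on it.
#'
#' @param tree A [neuron_tree()].
#' @return A tibble with columns `id` and `th` (empty for an empty tree).
#' @export
topological_height <- function(tree) {
  n <- nrow(tree)
  if (n == 0) return(tibble::tibble(id = integer(), th = integer()))
  kids <- children_index(tree)
  nk <- lengths(kids)
  th <- integer(n)
  ord <- rev(topological_order(tree)) # children before parents
  for (i in ord) {
    if (nk[i] == 0) {
      th[i] <- 1L
    } else if (nk[i] == 1) {
      th[i] <- th[kids[[i]][1]]
    } else {
      th[i] <- 1L + max(th[kids[[i]]])
    }
  }
  tibble::tibble(id = tree$id, th = th)
}

#' Recover reconstruction snapshots at evenly spaced time stages
#'
#' Divides the edit log's timeline (from first to last event timestamp) into
#' `n_stages` equal segments and replays all add/delete events up to each cut
#' time; confirmations do not change geometry. Stage `i`'s cut time is
#' `t_min + i * (t_max - t_min) / n_stages`, so the final stage is the full
#' replay.
#'
#' @param log An [edit_log()].
#' @param n_stages Number of stages (default 8).
#' @return A `stage_series`: list with `stages` (list of `neuron_tree`),
#'   `cut_times`, `n_stages` and the source `log`.
#' @export
stage_snapshots <- function(log, n_stages = 8) {
  events <- log_events(log)
  if (nrow(events) == 0) rlang::abort("cannot stage an empty edit log")
  t0 <- min(events$timestamp)
  t1 <- max(events$timestamp)
  cuts <- t0 + seq_len(n_stages) * (t1 - t0) / n_stages
  stages <- lapply(cuts, function(ct) replay_log(log, upto = ct))
  structure(
    list(stages = stages, cut_times = cuts, n_stages = n_stages, log = log),
    class = "stage_series"
  )
}

#' @export
print.stage_series <- function(x, ...) {
  cat(sprintf(
    "# stage_series: %d stages, %s nodes per stage\n", x$n_stages,
    paste(vapply(x$stages, nrow, integer(1)), collapse = "/")
  ))
  invisible(x)
}

# tree-maximum TH, 0 for an empty tree
max_th <- function(tree) {
  th <- topological_height(tree)
  if (nrow(th) == 0) 0L else max(th$th)
}

#' Normalised topological height across reconstruction stages
#'
#' NTH at stage \eqn{T_i} is the node's TH divided by the maximum TH observed
#' over all stages, \eqn{\mathrm{NTH}_{T_i} = \mathrm{TH}_{T_i} / \max_j
#' \mathrm{TH}_{T_j}}. The denominator is the per-neuron global maximum, never
#' a per-stage one, so NTH values are comparable across the timeline; they
#' lie in (0, 1] and are scale-free in the coordinates.
#'
#' @param series A `stage_series` from [stage_snapshots()], or a single
#'   [neuron_tree()] (treated as a one-stage series).
#' @return A tibble with columns `stage`, `id`, `th`, `nth`.
#' @export
normalized_topological_height <- function(series) {
  if (is_neuron_tree(series)) {
    series <- structure(
      list(stages = list(series), cut_times = NA_real_, n_stages = 1L),
      class = "stage_series"
    )
  }
  stopifnot(inherits(series, "stage_series"), length(series$stages) >= 1)
  denom <- max(vapply(series$stages, max_th, integer(1)))
  if (denom == 0) rlang::abort("all stages are empty; NTH is undefined")
  out <- lapply(seq_along(series$stages), function(i) {
    th <- topological_height(series$stages[[i]])
    th$stage <- i
    th
  })
  res <- dplyr::bind_rows(out)
  res$nth <- res$th / denom
  res[, c("stage", "id", "th", "nth")]
}

#' Matched and unmatched length by NTH bin and stage
#'
#' At every stage the snapshot is resampled, each resampled edge is labelled
#' matched or unmatched against the reference (the [match_length()]
#' machinery: the edge midpoint must lie within `dist_threshold` of the
#' resampled reference), and its length is accumulated into the NTH bin of
#' its child node. The NTH denominator is the global maximum TH over all
#' stages. Matched plus unmatched length per stage equals the stage's total
#' cable length.
#'
#' @param series A `stage_series`.
#' @param ref The reference (expert) [neuron_tree()]; must be non-empty.
#' @param bins Number of equal-width NTH bins on (0, 1].
#' @param dist_threshold Match distance in coordinate units (default two
#'   voxel lengths of `ref`).
#' @return An `nth_table` tibble with columns `stage`, `bin`, `nth_lo`,
#'   `nth_hi`, `matched_length`, `unmatched_length`.
#' @export
matched_unmatched_by_nth <- function(series, ref, bins = 10,
                                     dist_threshold = 2 * voxel_step(ref)) {
  stopifnot(inherits(series, "stage_series"))
  if (nrow(ref) == 0) rlang::abort("`ref` must be non-empty")
  denom <- max(vapply(series$stages, max_th, integer(1)))
  if (denom == 0) rlang::abort("all stages are empty")
  step <- min(voxel_step(ref), dist_threshold / 2)
  rs <- resample_tree(ref, step)
  ref_pts <- cbind(rs$x, rs$y, rs$z)
  breaks <- seq(0, 1, length.out = bins + 1)
  out <- list()
  for (si in seq_along(series$stages)) {
    st <- series$stages[[si]]
    if (nrow(st) == 0) next
    sr <- resample_tree(st, step)
    th <- topological_height(sr)$th
    prow <- match(sr$parent, sr$id)
    has <- !is.na(prow) & sr$parent != -1L
    if (!any(has)) next
    mid <- cbind(
      (sr$x[has] + sr$x[prow[has]]) / 2,
      (sr$y[has] + sr$y[prow[has]]) / 2,
      (sr$z[has] + sr$z[prow[has]]) / 2
    )
    len <- edge_lengths(sr)[has]
    matched <- nearest_points(mid, ref_pts)$distance <= dist_threshold
    nth <- th[has] / denom
    bin <- pmin(pmax(ceiling(nth * bins), 1L), bins)
    df <- tibble::tibble(bin = bin, len = len, matched = matched)
    agg <- dplyr::summarise(
      dplyr::group_by(df, bin),
      matched_length = sum(len[matched]),
      unmatched_length = sum(len[!matched]),
      .groups = "drop"
    )
    agg <- dplyr::left_join(tibble::tibble(bin = seq_len(bins)), agg, by = "bin")
    agg$matched_length[is.na(agg$matched_length)] <- 0
    agg$unmatched_length[is.na(agg$unmatched_length)] <- 0
    agg$stage <- si
    out[[length(out) + 1]] <- agg
  }
  res <- dplyr::bind_rows(out)
  res$nth_lo <- breaks[res$bin]
  res$nth_hi <- breaks[res$bin + 1]
  res <- res[, c("stage", "bin", "nth_lo", "nth_hi",
                 "matched_length", "unmatched_length")]
  class(res) <- c("nth_table", class(res))
  res
}
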