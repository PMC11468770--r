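#' Plot a neuron tree projection
#'
#' 2-D projection of the reconstruction's edges, coloured by structure type.
#'
#' @param tree A [neuron_tree()].
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @return A ggplot.
#' @export
plot_tree <- function(tree, plane = c("xy", "xz", "yz")) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  prow <- match(tree$parent, tree$id)
  has <- which(!is.na(prow) & tree$parent != -1L)
  seg <- tibble::tibble(
    x = tree[[ax[1]]][has], y = tree[[ax[2]]][has],
    xend = tree[[ax[1]]][prow[has]], yend = tree[[ax[2]]][prow[has]],
    type = factor(tree$type[has])
  )
  ggplot2::ggplot(seg, ggplot2::aes(
    x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
    colour = .data$type
  )) +
    ggplot2::geom_segment(linewidth = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = ax[1], y = ax[2], colour = "type") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nth_table <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("matched_length", "unmatched_length"),
    names_to = "status", values_to = "length"
  )
  df$status <- sub("_length", "", df$status)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$nth_lo, y = .data$length, fill = .data$status
  )) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~stage, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "normalised topological height",
                  y = "cable length", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.axon_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object), c("intensity", "radius"),
    names_to = "channel", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arc_pos, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(channel ~ branch, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "arc length (voxels)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.match_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tidy.match_report(object), c("matched_length", "unmatched_length"),
    names_to = "status", values_to = "length"
  )
  df$status <- sub("_length", "", df$status)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$side, y = .data$length,
                                   fill = .data$status)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "cable length", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Accuracy and agreement across reconstruction stages
#'
#' Recomputes, for each recovered stage, the accuracy against a reference
#' tree and (when the log is available) the agreement ratio, and plots both
#' against the stage index.
#'
#' @param series A `stage_series` from [stage_snapshots()].
#' @param ref Reference [neuron_tree()].
#' @param dist_threshold Match distance for [match_length()].
#' @return A ggplot.
#' @export
plot_stage_accuracy <- function(series, ref, dist_threshold = 2 * voxel_step(ref)) {
  acc <- vapply(series$stages, function(st) {
    match_length(st, ref, dist_threshold)$accuracy
  }, double(1))
  agr <- vapply(seq_along(series$stages), function(i) {
    st <- replay_state(series$log, upto = series$cut_times[i])
    if (length(Filter(function(s) !s$deleted, st$segments)) == 0) NA_real_
    else agreement(st)
  }, double(1))
  df <- tibble::tibble(
    stage = rep(seq_along(acc), 2),
    value = c(acc, agr),
    measure = rep(c("accuracy", "agreement"), each = length(acc))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$value,
                                   colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "stage", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
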