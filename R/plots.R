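# ggplot2 displays for records, detections and grid-search results.

#' Plot a PPG record
#'
#' @param object A `ppg_record`.
#' @param peaks Optional `peak_annotation` to overlay as points.
#' @param truth Optional ground-truth `peak_annotation`, overlaid as open
#'   circles.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppg_record <- function(object, peaks = NULL, truth = NULL, ...) {
  fs <- ppg_fs(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)", y = "amplitude (a.u.)",
      title = sprintf("PPG record %s (%g Hz)", attr(object, "record_id"), fs)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    ti <- peak_indices(truth)
    p <- p + ggplot2::geom_point(
      data = tibble(time = (ti - 1) / fs, amplitude = object$amplitude[ti]),
      shape = 1, size = 3, colour = "grey40"
    )
  }
  if (!is.null(peaks)) {
    pi <- peak_indices(peaks)
    p <- p + ggplot2::geom_point(
      data = tibble(time = (pi - 1) / fs, amplitude = object$amplitude[pi]),
      shape = 3, size = 2, colour = "red"
    )
  }
  p
}

#' Plot detections against ground truth
#'
#' Convenience wrapper over [autoplot.ppg_record()]: annotated peaks as open
#' circles, detections as crosses, so misses and extras are visible at a
#' glance.
#'
#' @param record A `ppg_record`.
#' @param detected A `peak_annotation` of detections.
#' @param truth Optional ground-truth `peak_annotation`.
#' @return A ggplot object.
#' @export
plot_detections <- function(record, detected, truth = NULL) {
  autoplot(record, peaks = detected, truth = truth)
}

#' Plot a grid-search result
#'
#' Tiles overall accuracy over the two moving-average windows, at the best
#' frequency band and offset for each (W1, W2) cell.
#'
#' @param object A `ppg_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppg_grid <- function(object, ...) {
  rows <- object$rows
  cell <- rows |>
    dplyr::group_by(.data$w1_ms, .data$w2_ms) |>
    dplyr::summarise(overall = max(.data$overall), .groups = "drop")
  ggplot2::ggplot(cell, ggplot2::aes(x = factor(.data$w1_ms),
                                     y = factor(.data$w2_ms),
                                     fill = .data$overall)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "overall", limits = c(NA, 1)) +
    ggplot2::labs(x = "systolic window W1 (ms)", y = "beat window W2 (ms)",
                  title = "Grid search: best overall accuracy per window pair") +
    ggplot2::theme_minimal()
}
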