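#' Plot simulated gyroscope segments
#'
#' Overlays the two channels of a few segments per motion, useful for
#' eyeballing the quasi-periodic burst structure of the simulated signals.
#'
#' @param dataset Segment tibble from [build_dataset()].
#' @param motions Motion ids to show.
#' @param n_segments Segments per motion to show.
#' @param fs Effective sampling rate (Hz) for the time axis.
#' @return A ggplot object.
#' @export
plot_segments <- function(dataset, motions = 1:8, n_segments = 1L,
                          fs = 133.4) {
  d <- dataset |>
    dplyr::filter(.data$motion_id %in% motions) |>
    dplyr::group_by(.data$motion_id, .data$channel) |>
    dplyr::slice_head(n = n_segments) |>
    dplyr::ungroup() |>
    dplyr::mutate(seg = paste0("M", .data$motion_id, " #",
                               .data$interval_index, ".",
                               .data$segment_index)) |>
    tidyr::unnest_longer(.data$samples, values_to = "rate") |>
    dplyr::group_by(.data$seg, .data$channel) |>
    dplyr::mutate(time = (dplyr::row_number() - 1) / fs) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$rate,
                                  colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~seg, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "angular rate (deg/s)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn level_scan Plot test and training accuracy against the
#'   decomposition level.
#' @param object A `level_scan` tibble.
#' @param ... Unused.
#' @export
autoplot.level_scan <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object[c("level", "train_accuracy", "test_accuracy")],
    cols = c("train_accuracy", "test_accuracy"),
    names_to = "set", values_to = "accuracy"
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$level, .data$accuracy,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(d$level)) +
    ggplot2::labs(x = "decomposition level",
                  y = "classification accuracy (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn wavelet_scan Plot the per-order test accuracy of each
#'   wavelet family.
#' @param object A `wavelet_scan`.
#' @param ... Unused.
#' @export
autoplot.wavelet_scan <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(.data$order, .data$test_accuracy)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~family, scales = "free_x") +
    ggplot2::labs(x = "order", y = "test accuracy (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @describeIn confusion_over_runs Heatmap of the mean confusion matrix
#'   with mean +/- sd labels.
#' @param object A `confusion_stats`.
#' @param ... Unused.
#' @export
autoplot.confusion_stats <- function(object, ...) {
  d <- tidy(object)
  d$true <- factor(d$true, levels = rev(rownames(object$mean)))
  d$classified <- factor(d$classified, levels = colnames(object$mean))
  ggplot2::ggplot(d, ggplot2::aes(.data$classified, .data$true,
                                  fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f±%.0f", .data$mean, .data$sd)
    ), size = 2.6) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "classified", y = "true", fill = "mean %") +
    ggplot2::theme_minimal()
}
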