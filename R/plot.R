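#' Plot a sensor stream
#'
#' One line per axis, faceted free-y, the usual way raw wearable traces are
#' inspected.
#'
#' @param object A [sensor_stream()] or [joint_stream()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensor_stream <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = -"time",
                              names_to = "axis", values_to = "value")
  unit <- if (sensor_kind(object) == "accelerometer") "g" else "rad/s"
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     color = .data$axis)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = paste0("signal (", unit, ")"),
                  title = paste0(sensor_kind(object), " stream")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @rdname autoplot.sensor_stream
#' @export
autoplot.joint_stream <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = -"time",
                              names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = JOINT_CHANNELS)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     color = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 3, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "signal (g | rad/s)",
                  title = "joint accelerometer + gyroscope stream") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a label series as an activity timeline
#'
#' @param object A [label_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.label_series <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = 1,
                                   fill = .data$label)) +
    ggplot2::geom_tile(height = 1) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "activity",
                  title = "classified activity timeline") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a heatmap
#'
#' Tiles show the column-normalized percentages (each truth column sums to
#' 100).
#'
#' @param object A [confusion_matrix()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.movelet_confusion <- function(object, ...) {
  long <- tidy(object)
  long$truth <- factor(long$truth, levels = object$truth_labels)
  long$predicted <- factor(long$predicted,
                           levels = rev(object$predicted_labels))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$truth, y = .data$predicted,
                                     fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$percent)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "ground truth", y = "predicted",
                  fill = "% of column") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
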