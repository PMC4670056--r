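#' Plot a metric histogram
#'
#' @param object A `metric_histogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot metric_histogram
#' @export
autoplot.metric_histogram <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_left + object$bin_width / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = object$bin_width, fill = "grey35") +
    ggplot2::labs(x = object$metric_name, y = "frequency") +
    ggplot2::theme_minimal()
}

#' Plot a threshold result: histogram with peaks and the interpeak minimum
#'
#' Mirrors the method's diagnostic figures: the metric histogram, its
#' detected peaks, and a dashed line at the interpeak-minimum threshold.
#'
#' @param object A `threshold_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot threshold_result
#' @export
autoplot.threshold_result <- function(object, ...) {
  d <- tidy(object)
  mid <- d$bin_left + object$histogram$bin_width / 2
  p <- autoplot(object$histogram) +
    ggplot2::geom_point(
      data = d[d$is_peak, ],
      ggplot2::aes(x = .data$bin_left + object$histogram$bin_width / 2,
                   y = .data$count),
      shape = 17, size = 3, color = "firebrick") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed")
  p
}

#' Plot an accuracy sweep
#'
#' Accuracy against candidate threshold, with a circle at the
#' interpeak-minimum threshold and a triangle at the brute-force best.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  g <- ggplot2::ggplot(object$grid,
                       ggplot2::aes(x = .data$threshold, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = tibble(threshold = object$best_threshold,
                    accuracy = object$best_accuracy),
      shape = 17, size = 3) +
    ggplot2::labs(x = "threshold", y = "accuracy (%)") +
    ggplot2::theme_minimal()
  if (!is.na(object$interpeak_threshold)) {
    g <- g + ggplot2::geom_point(
      data = tibble(threshold = object$interpeak_threshold,
                    accuracy = object$interpeak_accuracy),
      shape = 1, size = 3)
  }
  g
}

#' Plot a behavior assignment as a time band
#'
#' @param object A `behavior_assignment`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot behavior_assignment
#' @export
autoplot.behavior_assignment <- function(object, ...) {
  ggplot2::ggplot(object$labels,
                  ggplot2::aes(x = .data$time, y = 1, fill = .data$label)) +
    ggplot2::geom_tile(height = 1) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "behavior") +
    ggplot2::theme_minimal()
}

#' Plot a bout-averaging comparison
#'
#' The raw and segment-averaged accuracy sweeps side by side, showing the
#' elongated high-accuracy plateau produced by the bout-averaging
#' constraint.
#'
#' @param object A `bout_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bout_comparison
#' @export
autoplot.bout_comparison <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$raw$plateau_level,
                        linetype = "dotted") +
    ggplot2::facet_wrap(~variant) +
    ggplot2::labs(x = "threshold", y = "accuracy (%)") +
    ggplot2::theme_minimal()
}
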