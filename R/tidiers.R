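#' Tidy a metric histogram
#'
#' @param x A `metric_histogram`.
#' @param ... Unused.
#' @return A tibble with one row per bin: `bin_left`, `bin_right`, `count`.
#' @method tidy metric_histogram
#' @export
tidy.metric_histogram <- function(x, ...) {
  tibble(bin_left = x$bin_left_edges,
         bin_right = x$bin_left_edges + x$bin_width,
         count = x$counts)
}

#' @rdname tidy.metric_histogram
#' @method glance metric_histogram
#' @export
glance.metric_histogram <- function(x, ...) {
  tibble(metric = x$metric_name, bins = length(x$counts),
         bin_width = x$bin_width, n_binned = x$n_binned,
         n_dropped = x$n_dropped)
}

#' Tidy a threshold result
#'
#' `tidy()` returns the per-bin histogram annotated with which bins are
#' detected peaks and which is the interpeak minimum; `glance()` returns a
#' one-row summary with the threshold itself.
#'
#' @param x A `threshold_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy threshold_result
#' @export
tidy.threshold_result <- function(x, ...) {
  out <- tidy(x$histogram)
  out$is_peak <- seq_len(nrow(out)) %in% x$peaks$peak_bins
  out$is_minimum <- seq_len(nrow(out)) == x$minimum_bin
  out
}

#' @rdname tidy.threshold_result
#' @method glance threshold_result
#' @export
glance.threshold_result <- function(x, ...) {
  tibble(metric = x$histogram$metric_name, threshold = x$threshold,
         gap = x$gap, minimum_bin = x$minimum_bin,
         n_peaks = length(x$peaks$peak_bins),
         bin_width = x$histogram$bin_width)
}

#' Tidy an accuracy sweep
#'
#' `tidy()` returns the threshold/accuracy grid; `glance()` the one-row
#' summary (best and interpeak thresholds and accuracies, plateau width).
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sweep_result
#' @export
tidy.sweep_result <- function(x, ...) x$grid

#' @rdname tidy.sweep_result
#' @method glance sweep_result
#' @export
glance.sweep_result <- function(x, ...) {
  tibble(best_threshold = x$best_threshold, best_accuracy = x$best_accuracy,
         interpeak_threshold = x$interpeak_threshold,
         interpeak_accuracy = x$interpeak_accuracy,
         plateau_width = x$plateau_width, plateau_level = x$plateau_level)
}

#' Tidy a behavior assignment
#'
#' `tidy()` returns the per-second labels; `glance()` one row per step with
#' the thresholds used.
#'
#' @param x A `behavior_assignment` from [run_plan()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy behavior_assignment
#' @export
tidy.behavior_assignment <- function(x, ...) x$labels

#' @rdname tidy.behavior_assignment
#' @method glance behavior_assignment
#' @export
glance.behavior_assignment <- function(x, ...) {
  bind_rows(lapply(seq_along(x$thresholds), function(i) {
    g <- glance(x$thresholds[[i]])
    g$step <- i
    g
  }))[, c("step", "metric", "threshold", "gap", "minimum_bin", "n_peaks",
          "bin_width")]
}

#' Tidy a bout-averaging comparison
#'
#' @param x A `bout_comparison`.
#' @param ... Unused.
#' @return `tidy()`: the two sweep grids stacked with a `variant` column;
#'   `glance()`: one row with the accuracy and plateau gains.
#' @method tidy bout_comparison
#' @export
tidy.bout_comparison <- function(x, ...) {
  bind_rows(
    mutate(x$raw$grid, variant = "raw"),
    mutate(x$averaged$grid, variant = "averaged")
  )
}

#' @rdname tidy.bout_comparison
#' @method glance bout_comparison
#' @export
glance.bout_comparison <- function(x, ...) {
  tibble(raw_interpeak_accuracy = x$raw$interpeak_accuracy,
         averaged_interpeak_accuracy = x$averaged$interpeak_accuracy,
         accuracy_gain = x$accuracy_gain,
         raw_plateau_width = x$raw$plateau_width,
         averaged_plateau_width = x$averaged$plateau_width,
         plateau_gain = x$plateau_gain)
}
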