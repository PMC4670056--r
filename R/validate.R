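#' Per-second assignment accuracy against known labels
#'
#' The percentage of seconds whose predicted behavior equals the known
#' behavior, optionally restricted to seconds whose true label is in
#' `scope`.
#'
#' @param predicted,truth Character label vectors of equal length, or label
#'   tibbles with a `label` column.
#' @param scope Optional character vector of true labels to score over;
#'   `NULL` scores every second.
#' @return Accuracy as a percentage in \[0, 100\].
#' @export
#' @examples
#' accuracy(c("A", "A", "B", "B"), c("A", "B", "B", "B"))  # 75
accuracy <- function(predicted, truth, scope = NULL) {
  predicted <- label_vector(predicted)
  truth <- label_vector(truth)
  if (length(predicted) != length(truth)) {
    stop_ethopeak(
      sprintf("predicted (%d) and truth (%d) differ in length",
              length(predicted), length(truth)),
      "alignment_error")
  }
  keep <- if (is.null(scope)) rep(TRUE, length(truth)) else truth %in% scope
  if (!any(keep)) {
    stop_ethopeak("no seconds fall within the requested scope: accuracy undefined",
                  "empty_input")
  }
  100 * mean(predicted[keep] == truth[keep])
}

label_vector <- function(x) {
  if (is.data.frame(x)) as.character(x$label) else as.character(x)
}

#' Accuracy sweep over a range of candidate thresholds
#'
#' Re-assigns the two behaviors at every candidate threshold on a uniform
#' grid and scores each assignment against the known labels, reproducing the
#' validation design of the method: the grid step defaults to the histogram
#' bin width, the best threshold (ties to the lowest) is found by brute
#' force, the interpeak-minimum threshold is scored for comparison, and the
#' width of the contiguous plateau with accuracy at or above
#' `plateau_level` is reported.
#'
#' @param metric Per-second numeric vector (possibly bout-averaged).
#' @param truth Known labels (vector or tibble with `label`), using the same
#'   two names as `below_label`/`above_label`; other true labels count as
#'   mismatches unless masked out.
#' @param lo,hi,step Threshold grid: `seq(lo, hi, by = step)`.
#' @param below_label,above_label Behaviors assigned below / at-or-above
#'   each candidate threshold.
#' @param interpeak Optional `threshold_result` (or bare number): the
#'   objective threshold to score alongside the sweep.
#' @param mask Logical vector of seconds to score (default: all).
#' @param plateau_level Accuracy level (percent) defining the plateau.
#' @return A `sweep_result`: list with `grid` (tibble `threshold`,
#'   `accuracy`), `best_threshold`, `best_accuracy`,
#'   `interpeak_threshold`, `interpeak_accuracy` (NA when no interpeak
#'   threshold was supplied), `plateau_width`, `plateau_level`, `step`.
#' @export
threshold_sweep <- function(metric, truth, lo, hi, step,
                            below_label, above_label,
                            interpeak = NULL, mask = NULL,
                            plateau_level = 95) {
  if (!(lo < hi) || step <= 0) {
    stop_ethopeak("need lo < hi and step > 0", "validation_error")
  }
  truth <- label_vector(truth)
  mask <- mask %||% rep(TRUE, length(metric))
  thresholds <- seq(lo, hi, by = step)
  score_at <- function(thr) {
    pred <- assign_by_threshold(metric, thr, below_label, above_label,
                                mask = mask)
    accuracy(pred[mask], truth[mask])
  }
  acc <- vapply(thresholds, score_at, numeric(1))
  best_i <- which.max(acc)              # which.max takes the first (lowest) tie
  ip_thr <- if (inherits(interpeak, "threshold_result")) {
    interpeak$threshold
  } else if (is.numeric(interpeak)) {
    interpeak
  } else {
    NA_real_
  }
  ip_acc <- if (is.na(ip_thr)) NA_real_ else score_at(ip_thr)
  on_plateau <- acc >= plateau_level
  plateau_width <- if (any(on_plateau)) {
    r <- rle(on_plateau)
    max(r$lengths[r$values]) * step
  } else {
    0
  }
  structure(
    list(grid = tibble(threshold = thresholds, accuracy = acc),
         best_threshold = thresholds[best_i], best_accuracy = acc[best_i],
         interpeak_threshold = ip_thr, interpeak_accuracy = ip_acc,
         plateau_width = plateau_width, plateau_level = plateau_level,
         step = step,
         below_label = below_label, above_label = above_label),
    class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "<sweep_result> %s | %s over [%g, %g] by %g\n",
    x$below_label, x$above_label, min(x$grid$threshold),
    max(x$grid$threshold), x$step))
  cat(sprintf("  best: %.2f%% at %g; interpeak: %.2f%% at %g; plateau >= %g%%: %g wide\n",
              x$best_accuracy, x$best_threshold,
              x$interpeak_accuracy, x$interpeak_threshold,
              x$plateau_level, x$plateau_width))
  invisible(x)
}

#' Ground-truth labels from a salt-water immersion logger
#'
#' Epochs with immersion value at or above `wet_min` become `wet_label`,
#' the rest `dry_label`; each epoch label is repeated across its seconds so
#' the result aligns with a per-second metric table.
#'
#' @param immersion Immersion tibble (columns `time` = epoch end, `value`;
#'   attribute or argument `epoch_seconds`).
#' @param wet_label,dry_label Behavior names to emit.
#' @param wet_min Minimum value (of 0-200) for an epoch to count as wet;
#'   default 1, i.e. any immersion at all.
#' @param epoch_seconds Epoch duration; defaults to the series attribute,
#'   else 600 s.
#' @return A label tibble (`time`, `label`) at 1-second resolution.
#' @export
immersion_to_truth <- function(immersion, wet_label = "on_water",
                               dry_label = "dry", wet_min = 1,
                               epoch_seconds = NULL) {
  epoch_seconds <- epoch_seconds %||% attr(immersion, "epoch_seconds") %||% 600
  epoch_labels <- ifelse(immersion$value >= wet_min, wet_label, dry_label)
  labels <- rep(epoch_labels, each = epoch_seconds)
  t0 <- immersion$time[1] - epoch_seconds
  tibble(time = t0 + seq_along(labels) - 1, label = labels)
}

#' Effect of the bout-averaging constraint on a posture step
#'
#' Runs the plan's bout-constrained step both ways — thresholding the raw
#' per-second metric and the segment-averaged metric — over the same
#' threshold grid, and reports the accuracy and plateau-width differences.
#' Averaging posture between bouts of the anchor behavior separates the
#' histogram modes further and widens the high-accuracy plateau.
#'
#' @param metrics Metric tibble from [compute_metrics()].
#' @param plan A [classification_plan()] containing a bout-constrained step.
#' @param truth Known labels (vector or tibble with `label`), aligned to
#'   `metrics`.
#' @param lo,hi,step Threshold grid for both sweeps.
#' @inheritParams threshold_sweep
#' @param bin_widths,peak_args Passed to [run_plan()] for the preceding steps.
#' @return A `bout_comparison`: list with `raw` and `averaged`
#'   `sweep_result`s, `accuracy_gain` (averaged minus raw, at the interpeak
#'   threshold) and `plateau_gain`.
#' @export
bout_averaging_comparison <- function(metrics, plan, truth, lo, hi, step,
                                      plateau_level = 95,
                                      bin_widths = NULL, peak_args = list()) {
  idx <- which(vapply(plan$steps,
                      function(s) !is.null(s$bout_constraint), logical(1)))
  if (length(idx) == 0L) {
    stop_ethopeak("plan has no bout-constrained step", "validation_error")
  }
  idx <- idx[1]
  s <- plan$steps[[idx]]
  truth <- label_vector(truth)

  # run the preceding steps to obtain the anchor bouts and eligibility
  pre_plan <- structure(
    list(vocabulary = plan$vocabulary, steps = plan$steps[seq_len(idx - 1)]),
    class = "classification_plan")
  pre <- run_plan(metrics, pre_plan, bin_widths = bin_widths,
                  peak_args = peak_args)
  labels <- pre$labels$label
  eligible <- if (identical(s$applies_to, "unassigned")) {
    labels == "unassigned"
  } else {
    labels %in% s$applies_to
  }
  scope <- if (s$histogram_scope == "all") rep(TRUE, nrow(metrics)) else eligible
  bw <- bin_widths[s$metric] %||% s$bin_width
  if (!is.null(bw) && is.na(bw)) bw <- s$bin_width
  thr <- do.call(threshold_from_values,
                 c(list(metrics[[s$metric]][scope], bin_width = bw,
                        expected_k = s$expected_k, gap = s$gap), peak_args))
  thr$histogram$metric_name <- s$metric

  raw_metric <- metrics[[s$metric]]
  segs <- bout_segments(labels, s$bout_constraint$anchor,
                        s$bout_constraint$min_bout_seconds)
  avg_metric <- average_within_segments(raw_metric, segs)

  score_mask <- eligible & truth %in% c(s$below, s$above)
  raw_sweep <- threshold_sweep(raw_metric, truth, lo, hi, step,
                               s$below, s$above, interpeak = thr,
                               mask = score_mask,
                               plateau_level = plateau_level)
  avg_sweep <- threshold_sweep(avg_metric, truth, lo, hi, step,
                               s$below, s$above, interpeak = thr,
                               mask = score_mask,
                               plateau_level = plateau_level)
  structure(
    list(raw = raw_sweep, averaged = avg_sweep,
         accuracy_gain = avg_sweep$interpeak_accuracy - raw_sweep$interpeak_accuracy,
         plateau_gain = avg_sweep$plateau_width - raw_sweep$plateau_width),
    class = "bout_comparison")
}

#' @export
print.bout_comparison <- function(x, ...) {
  cat("<bout_comparison> raw vs bout-averaged posture thresholding\n")
  cat(sprintf("  interpeak accuracy: %.2f%% -> %.2f%% (gain %.2f points)\n",
              x$raw$interpeak_accuracy, x$averaged$interpeak_accuracy,
              x$accuracy_gain))
  cat(sprintf("  plateau width at >= %g%%: %g -> %g (gain %g)\n",
              x$raw$plateau_level, x$raw$plateau_width,
              x$averaged$plateau_width, x$plateau_gain))
  invisible(x)
}
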