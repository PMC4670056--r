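#' Declare one stepwise classification step
#'
#' Each step separates one behavior from the rest: it histograms a metric
#' over a chosen subset of seconds, locates an interpeak-minimum threshold,
#' and labels eligible seconds below/above that threshold. Steps are applied
#' in order, most distinct behavior first (e.g. flight before the stationary
#' behaviors; sitting before walking/running).
#'
#' @param metric Name of a metric column produced by [compute_metrics()].
#' @param expected_k Number of modes expected in the metric's histogram.
#' @param gap Which interpeak gap supplies the threshold (1 = between first
#'   and second peak).
#' @param below,above Behavior assigned to eligible seconds with metric
#'   strictly below / at-or-above the threshold.
#' @param applies_to Which seconds the step may label: `"unassigned"`
#'   (default) or a character vector of labels produced by earlier steps.
#' @param bin_width Histogram bin width; `NULL` uses the metric's default
#'   (0.02 g for acceleration metrics, 1 degree for angles).
#' @param histogram_scope Seconds used to build the threshold histogram:
#'   `"eligible"` (default; e.g. with already-assigned flight removed) or
#'   `"all"` (the full deployment, e.g. a trimodal histogram whose later
#'   gaps are used after earlier behaviors were peeled off).
#' @param bout_constraint Optional [bout_constraint()]: before thresholding,
#'   replace the metric by its mean within each segment between bouts of the
#'   anchor behavior. The threshold still comes from the un-averaged
#'   histogram.
#' @return A `classification_step` list.
#' @export
classification_step <- function(metric, expected_k, gap, below, above,
                                applies_to = "unassigned", bin_width = NULL,
                                histogram_scope = c("eligible", "all"),
                                bout_constraint = NULL) {
  structure(
    list(metric = metric, expected_k = as.integer(expected_k),
         gap = as.integer(gap), below = below, above = above,
         applies_to = applies_to, bin_width = bin_width,
         histogram_scope = match.arg(histogram_scope),
         bout_constraint = bout_constraint),
    class = "classification_step")
}

#' Bout-averaging constraint for a posture-based step
#'
#' Encodes a biological transition rule: behaviors on either side of the
#' threshold can only alternate across a bout of the anchor behavior (a
#' cliff-nesting seabird must fly to move between land and water). The
#' step's metric is replaced by its mean over each segment between
#' consecutive anchor bouts, so every between-bout segment receives a single
#' label.
#'
#' @param anchor Behavior whose bouts delimit the segments; must be assigned
#'   by an earlier step.
#' @param aggregate Segment aggregate; only `"mean"` is defined.
#' @param min_bout_seconds Anchor runs shorter than this do not count as
#'   bouts (default 1: every run counts).
#' @return A `bout_constraint` list.
#' @export
bout_constraint <- function(anchor, aggregate = "mean", min_bout_seconds = 1L) {
  if (!identical(aggregate, "mean")) {
    stop_ethopeak("only aggregate = 'mean' is supported", "validation_error")
  }
  structure(list(anchor = anchor, aggregate = aggregate,
                 min_bout_seconds = as.integer(min_bout_seconds)),
            class = "bout_constraint")
}

metric_names <- c("mean_surge", "mean_sway", "mean_heave",
                  "sd_surge", "sd_sway", "sd_heave",
                  "pitch", "roll", "odba", "vedba")

#' Assemble and validate a stepwise classification plan
#'
#' @param vocabulary Character vector of all behavior names the plan can
#'   produce (intermediate labels such as "nonflight" included);
#'   `"unassigned"` is implicitly reserved.
#' @param steps List of [classification_step()]s, applied in order.
#' @return A `classification_plan`. All validation violations are reported
#'   together.
#' @export
classification_plan <- function(vocabulary, steps) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  vocabulary <- as.character(vocabulary)
  producible <- character(0)
  assigned_so_far <- character(0)
  for (i in seq_along(steps)) {
    s <- steps[[i]]
    pre <- sprintf("step %d: ", i)
    if (!s$metric %in% metric_names) {
      add(paste0(pre, sprintf("unknown metric '%s'", s$metric)))
    }
    if (!is.null(s$bin_width) && (!is.finite(s$bin_width) || s$bin_width <= 0)) {
      add(paste0(pre, sprintf("bin_width must be positive, got %g", s$bin_width)))
    }
    if (is.na(s$gap) || is.na(s$expected_k) ||
        s$gap < 1L || s$gap > s$expected_k - 1L) {
      add(paste0(pre, sprintf("gap %s must lie in 1..expected_k-1 (expected_k = %s)",
                              s$gap, s$expected_k)))
    }
    if (identical(s$below, s$above)) {
      add(paste0(pre, "below and above labels must differ"))
    }
    for (lab in c(s$below, s$above)) {
      if (!lab %in% vocabulary) {
        add(paste0(pre, sprintf("label '%s' is not in the vocabulary", lab)))
      }
    }
    if (!identical(s$applies_to, "unassigned") &&
        !all(s$applies_to %in% assigned_so_far)) {
      add(paste0(pre, sprintf(
        "applies_to '%s' is not produced by an earlier step",
        paste(setdiff(s$applies_to, assigned_so_far), collapse = ", "))))
    }
    if (!is.null(s$bout_constraint) &&
        !s$bout_constraint$anchor %in% assigned_so_far) {
      add(paste0(pre, sprintf(
        "bout_constraint anchor '%s' is not assigned by an earlier step",
        s$bout_constraint$anchor)))
    }
    assigned_so_far <- union(assigned_so_far, c(s$below, s$above))
    producible <- union(producible, c(s$below, s$above))
  }
  orphans <- setdiff(vocabulary, producible)
  if (length(steps) > 0 && length(orphans) > 0) {
    add(sprintf("vocabulary label(s) not producible by any step: %s",
                paste(orphans, collapse = ", ")))
  }
  if (length(problems) > 0) {
    stop_ethopeak(paste(c("invalid classification plan:", problems),
                        collapse = "\n  "), "validation_error")
  }
  structure(list(vocabulary = vocabulary, steps = steps),
            class = "classification_plan")
}

#' @export
print.classification_plan <- function(x, ...) {
  cat(sprintf("<classification_plan> %d step(s); vocabulary: %s\n",
              length(x$steps), paste(x$vocabulary, collapse = ", ")))
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat(sprintf("  %d. %s (k = %d, gap %d): < thr -> %s, >= thr -> %s%s%s\n",
                i, s$metric, s$expected_k, s$gap, s$below, s$above,
                if (identical(s$applies_to, "unassigned")) ""
                else paste0(" [on ", paste(s$applies_to, collapse = "/"), "]"),
                if (is.null(s$bout_constraint)) ""
                else paste0(" [bout-averaged between '",
                            s$bout_constraint$anchor, "' bouts]")))
  }
  invisible(x)
}

#' Label seconds on either side of a threshold
#'
#' Eligible seconds with metric strictly below the threshold receive
#' `below_label`; seconds at or above it receive `above_label` (a value
#' exactly at the threshold is "above", consistent with the threshold being
#' the right edge of the interpeak-minimum bin). Ineligible seconds keep
#' their previous label. Non-finite metric values at eligible seconds are
#' labeled `"unassigned"` with a message.
#'
#' @param metric Per-second numeric vector.
#' @param threshold Threshold in metric units.
#' @param below_label,above_label Behavior names.
#' @param mask Logical vector of eligible seconds (default: all).
#' @param labels Existing label vector to fill in (default `"unassigned"`).
#' @return Character label vector of `length(metric)`.
#' @export
assign_by_threshold <- function(metric, threshold, below_label, above_label,
                                mask = NULL, labels = NULL) {
  n <- length(metric)
  mask <- mask %||% rep(TRUE, n)
  labels <- labels %||% rep("unassigned", n)
  if (length(mask) != n || length(labels) != n) {
    stop_ethopeak("metric, mask and labels must have equal length",
                  "alignment_error")
  }
  bad <- mask & !is.finite(metric)
  if (any(bad)) {
    inform(sprintf("%d eligible second(s) with non-finite metric left unassigned",
                   sum(bad)))
    labels[bad] <- "unassigned"
  }
  ok <- mask & !bad
  labels[ok & metric < threshold] <- below_label
  labels[ok & metric >= threshold] <- above_label
  labels
}

#' Segments between bouts of an anchor behavior
#'
#' A bout is a maximal run of the anchor label (runs shorter than
#' `min_bout_seconds` are not bouts). The segments are the maximal runs of
#' remaining seconds: disjoint, covering every non-bout second, including
#' the stretch before the first bout and after the last. With no anchor
#' bouts at all there is a single segment spanning the series.
#'
#' @param labels Character label vector (per second).
#' @param anchor_label The anchor behavior.
#' @param min_bout_seconds Minimum run length for an anchor run to count.
#' @return A tibble with columns `start`, `end` (1-based, inclusive).
#' @export
#' @examples
#' bout_segments(c("F", "F", "N", "N", "N", "F", "N", "N"), "F")
bout_segments <- function(labels, anchor_label, min_bout_seconds = 1L) {
  r <- rle(labels == anchor_label)
  is_bout_run <- r$values & r$lengths >= min_bout_seconds
  in_bout <- rep(is_bout_run, r$lengths)   # anchor runs below the minimum
  r2 <- rle(!in_bout)                      # duration merge into segments
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1L
  tibble(start = starts[r2$values], end = ends[r2$values])
}

#' Replace a metric by its mean within each segment
#'
#' Every second inside a segment carries that segment's mean metric value;
#' seconds outside all segments are unchanged.
#'
#' @param metric Per-second numeric vector.
#' @param segments Tibble of disjoint `start`/`end` intervals
#'   (from [bout_segments()]).
#' @return Numeric vector of `length(metric)`.
#' @export
average_within_segments <- function(metric, segments) {
  out <- metric
  for (i in seq_len(nrow(segments))) {
    idx <- segments$start[i]:segments$end[i]
    out[idx] <- mean(metric[idx])
  }
  out
}

#' Run a stepwise classification plan over a metric table
#'
#' Executes the plan one step at a time. Each step (i) histograms its metric
#' over the in-scope seconds (by default the still-eligible ones, so data
#' already assigned to earlier behaviors are removed before
#' re-histogramming), (ii) locates the interpeak-minimum threshold, and
#' (iii) labels the eligible seconds. A bout-constrained step averages its
#' metric within each segment between anchor bouts before applying the
#' threshold, but the threshold itself always comes from the histogram of
#' the metric *before* averaging.
#'
#' @param metrics Metric tibble from [compute_metrics()].
#' @param plan A [classification_plan()].
#' @param bin_widths Optional named numeric vector overriding bin widths per
#'   metric, e.g. `c(sd_heave = 0.01, pitch = 2)`.
#' @param peak_args Optional list of extra arguments for [find_peaks()]
#'   (`min_separation`, `prominence`, `smooth_span`).
#' @return A `behavior_assignment` object: list with `labels` (tibble `t`,
#'   `label`), `thresholds` (one `threshold_result` per step, named by
#'   step), `plan`.
#' @export
run_plan <- function(metrics, plan, bin_widths = NULL, peak_args = list()) {
  stopifnot(inherits(plan, "classification_plan"))
  n <- nrow(metrics)
  labels <- rep("unassigned", n)
  audits <- vector("list", length(plan$steps))
  for (i in seq_along(plan$steps)) {
    s <- plan$steps[[i]]
    eligible <- if (identical(s$applies_to, "unassigned")) {
      labels == "unassigned"
    } else {
      labels %in% s$applies_to
    }
    scope <- if (s$histogram_scope == "all") rep(TRUE, n) else eligible
    bw <- bin_widths[s$metric] %||% s$bin_width
    if (!is.null(bw) && is.na(bw)) bw <- s$bin_width
    vals <- metrics[[s$metric]][scope]
    thr <- tryCatch(
      do.call(threshold_from_values,
              c(list(vals, bin_width = bw, expected_k = s$expected_k,
                     gap = s$gap), peak_args)),
      ethopeak_error = function(e) {
        stop_ethopeak(sprintf("step %d (%s): %s", i, s$metric,
                              conditionMessage(e)),
                      "modality_error", parent = e)
      })
    thr$histogram$metric_name <- s$metric
    metric_vals <- metrics[[s$metric]]
    if (!is.null(s$bout_constraint)) {
      segs <- bout_segments(labels, s$bout_constraint$anchor,
                            s$bout_constraint$min_bout_seconds)
      metric_vals <- average_within_segments(metric_vals, segs)
    }
    labels <- assign_by_threshold(metric_vals, thr$threshold,
                                  s$below, s$above,
                                  mask = eligible, labels = labels)
    audits[[i]] <- thr
  }
  names(audits) <- vapply(plan$steps, function(s) s$metric, character(1))
  structure(
    list(labels = tibble(time = metrics$t, label = labels),
         thresholds = audits,
         plan = plan),
    class = "behavior_assignment")
}

#' @export
print.behavior_assignment <- function(x, ...) {
  tab <- table(x$labels$label)
  cat(sprintf("<behavior_assignment> %d s labeled via %d step(s)\n",
              nrow(x$labels), length(x$thresholds)))
  for (nm in names(tab)) {
    cat(sprintf("  %-12s %6d s (%.1f%%)\n", nm, tab[[nm]],
                100 * tab[[nm]] / nrow(x$labels)))
  }
  for (i in seq_along(x$thresholds)) {
    t <- x$thresholds[[i]]
    cat(sprintf("  step %d: %s threshold %g\n", i,
                t$histogram$metric_name, t$threshold))
  }
  invisible(x)
}

#' Threshold audit trail of a run as JSON
#'
#' Per step: metric, threshold, interpeak gap, minimum bin, peak bins and
#' bin width — enough to reproduce every assignment decision.
#'
#' @param assignment A `behavior_assignment` from [run_plan()].
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_threshold_audit <- function(assignment, path) {
  audit <- lapply(seq_along(assignment$thresholds), function(i) {
    t <- assignment$thresholds[[i]]
    list(step = i, metric = t$histogram$metric_name,
         threshold = t$threshold, gap = t$gap,
         minimum_bin = t$minimum_bin,
         peak_bins = t$peaks$peak_bins,
         bin_width = t$histogram$bin_width)
  })
  jsonlite::write_json(audit, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
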