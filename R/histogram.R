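#' Bin a metric into a uniform frequency histogram
#'
#' Bins are contiguous, uniform, left-closed and right-open. When no range is
#' given it is the data range padded outward to whole multiples of
#' `bin_width`. Non-finite values are excluded (with a message giving the
#' count); with an explicit range, values outside it are likewise excluded.
#'
#' @param data A data frame holding the metric, or a bare numeric vector.
#' @param metric Column holding the metric (tidy-eval); ignored when `data`
#'   is a vector.
#' @param bin_width Bin width in metric units (g or degrees). Defaults to
#'   0.02 g for acceleration-derived metrics and 1 degree for `pitch`/`roll`
#'   when the metric name is recognized, otherwise it must be given.
#' @param range Optional `c(lo, hi)` limits; bins cover `[lo, hi)`.
#' @return A `metric_histogram` object: list with `bin_width`,
#'   `bin_left_edges`, `counts`, `metric_name`, `n_binned`, `n_dropped`.
#' @export
#' @examples
#' h <- metric_histogram(c(0.01, 0.03, 0.03), bin_width = 0.02, range = c(0, 0.06))
#' h$counts  # 1 2 0
metric_histogram <- function(data, metric = NULL, bin_width = NULL,
                             range = NULL) {
  if (is.data.frame(data)) {
    metric_q <- enquo(metric)
    if (rlang::quo_is_null(metric_q)) {
      stop_ethopeak("supply the metric column to histogram", "validation_error")
    }
    metric_name <- as_name(metric_q)
    if (!metric_name %in% names(data)) {
      stop_ethopeak(sprintf("metric column '%s' not found", metric_name),
                    "validation_error")
    }
    values <- data[[metric_name]]
  } else {
    values <- as.numeric(data)
    metric_name <- "metric"
  }
  bin_width <- bin_width %||% default_bin_width(metric_name)
  if (is.null(bin_width) || !is.finite(bin_width) || bin_width <= 0) {
    stop_ethopeak("bin_width must be a positive number", "validation_error")
  }
  finite <- is.finite(values)
  n_dropped <- sum(!finite)
  values <- values[finite]
  if (length(values) == 0L) {
    stop_ethopeak("no finite values to histogram", "empty_input")
  }
  if (is.null(range)) {
    lo <- floor(min(values) / bin_width) * bin_width
    hi <- floor(max(values) / bin_width) * bin_width + bin_width
  } else {
    lo <- range[1]; hi <- range[2]
    if (!(lo < hi)) stop_ethopeak("range must satisfy lo < hi", "validation_error")
    inside <- values >= lo & values < hi
    n_dropped <- n_dropped + sum(!inside)
    values <- values[inside]
    if (length(values) == 0L) {
      stop_ethopeak("no values inside the requested range", "empty_input")
    }
  }
  n_bins <- max(1L, as.integer(ceiling((hi - lo) / bin_width - 1e-9)))
  idx <- pmin(floor((values - lo) / bin_width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  if (n_dropped > 0L) {
    inform(sprintf("%d value(s) excluded from the histogram", n_dropped))
  }
  structure(
    list(bin_width = bin_width,
         bin_left_edges = lo + (seq_len(n_bins) - 1L) * bin_width,
         counts = counts,
         metric_name = metric_name,
         n_binned = length(values),
         n_dropped = n_dropped),
    class = "metric_histogram")
}

default_bin_width <- function(metric_name) {
  if (metric_name %in% c("pitch", "roll")) return(1)
  if (grepl("^(sd|mean)_|^(odba|vedba)$", metric_name)) return(0.02)
  NULL
}

#' @export
print.metric_histogram <- function(x, ...) {
  cat(sprintf("<metric_histogram> %s: %d bins of width %g over [%g, %g), n = %d\n",
              x$metric_name, length(x$counts), x$bin_width,
              x$bin_left_edges[1],
              x$bin_left_edges[length(x$counts)] + x$bin_width, x$n_binned))
  invisible(x)
}

smooth_counts <- function(counts, span = 3L) {
  # centered moving mean with shrinking windows at the edges, so terminal
  # bins can still qualify as maxima
  n <- length(counts)
  half <- (span - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    j <- max(1L, i - half):min(n, i + half)
    mean(counts[j])
  }, numeric(1))
}

local_maxima <- function(s) {
  n <- length(s)
  if (n == 1L) return(1L)
  left_ok <- c(TRUE, s[-1] > s[-n])              # rises into i (plateau: first bin wins)
  right_ok <- c(s[-n] >= s[-1], TRUE)            # does not rise after i
  which(left_ok & right_ok)
}

# topographic prominence: height above the key saddle, i.e. the deeper of the
# two valley minima separating the peak from higher ground (or the series
# edge). Scale-robust: sub-lumps riding on one mode have shallow saddles and
# low prominence regardless of bin width.
peak_prominence <- function(s, i) {
  n <- length(s)
  side_base <- function(idx) {
    if (length(idx) == 0L) return(NA_real_)
    higher <- which(s[idx] > s[i])
    # no higher ground before the edge: the side is unbounded, no saddle
    if (length(higher) == 0L) return(NA_real_)
    idx <- idx[seq_len(higher[1] - 1L)]
    if (length(idx) == 0L) return(s[i])
    min(s[idx])
  }
  left <- side_base(rev(seq_len(i - 1L)))
  right <- side_base(if (i < n) (i + 1L):n else integer(0))
  base <- suppressWarnings(max(left, right, na.rm = TRUE))
  if (!is.finite(base)) return(s[i])
  s[i] - base
}

#' Locate the modes of a metric histogram
#'
#' Identifies the `expected_k` dominant modes: counts are lightly smoothed
#' (centered 3-bin moving mean) for detection only, each local maximum is
#' scored by its topographic prominence (height above the deeper of the two
#' valley minima separating it from higher ground), maxima with prominence
#' below `prominence` of the global maximum are discarded, and the
#' `expected_k` most prominent maxima at least `min_separation` bins apart
#' are kept (ties broken toward the lower bin). Prominence rather than raw
#' height makes detection robust to bin width: small lumps riding on a mode
#' have shallow saddles and never outrank a genuine second mode. Peaks are
#' returned in increasing bin order. Histograms of movement metrics are bimodal for a flying seabird
#' (stationary vs flight) and trimodal for a human sitting/walking/running.
#'
#' @param hist A `metric_histogram`.
#' @param expected_k Number of modes expected (>= 2).
#' @param min_separation Minimum distance between selected peaks, in bins.
#' @param prominence Minimum topographic prominence as a fraction of the
#'   global smoothed maximum.
#' @param smooth_span Width of the detection smoother, in bins.
#' @return A `peak_set`: list with `peak_bins` (1-based bin indices),
#'   `expected_k`, `prominence`.
#' @export
find_peaks <- function(hist, expected_k, min_separation = 3L,
                       prominence = 0.05, smooth_span = 3L) {
  stopifnot(inherits(hist, "metric_histogram"))
  if (expected_k < 2L) {
    stop_ethopeak("expected_k must be at least 2", "validation_error")
  }
  if (sum(hist$counts > 0) < expected_k) {
    stop_ethopeak(
      sprintf("histogram has %d non-empty bins but %d modes are expected",
              sum(hist$counts > 0), expected_k),
      "modality_error")
  }
  s <- smooth_counts(hist$counts, span = smooth_span)
  cand <- local_maxima(s)
  prom <- vapply(cand, function(i) peak_prominence(s, i), numeric(1))
  keep <- prom >= prominence * max(s) & s[cand] > 0
  cand <- cand[keep]
  prom <- prom[keep]
  # greedy pick by descending prominence, lower bin first on ties
  ord <- cand[order(-prom, cand)]
  picked <- integer(0)
  for (b in ord) {
    if (length(picked) == expected_k) break
    if (all(abs(picked - b) >= min_separation)) picked <- c(picked, b)
  }
  if (length(picked) < expected_k) {
    stop_ethopeak(
      sprintf(paste0("found %d qualifying mode(s) but %d expected; ",
                     "adjust bin_width, expected_k or the peak constraints"),
              length(picked), expected_k),
      "modality_error")
  }
  structure(list(peak_bins = sort(picked), expected_k = as.integer(expected_k),
                 prominence = prominence),
            class = "peak_set")
}

#' Interpeak frequency minimum of a histogram
#'
#' The objective threshold of the method: the bin of lowest raw count lying
#' strictly between two adjacent detected peaks. Ties go to the lower bin;
#' the threshold value is the right edge of the minimum bin, so data in the
#' minimum bin itself fall below the threshold.
#'
#' @param hist A `metric_histogram`.
#' @param peaks A `peak_set` from [find_peaks()].
#' @param gap Which interpeak gap to use: 1 = between the first and second
#'   peak, 2 = between the second and third, ...
#' @return A `threshold_result`: list with `threshold`, `gap`,
#'   `minimum_bin` (1-based), `histogram`, `peaks`.
#' @export
interpeak_minimum <- function(hist, peaks, gap = 1L) {
  stopifnot(inherits(hist, "metric_histogram"), inherits(peaks, "peak_set"))
  gap <- as.integer(gap)
  k <- length(peaks$peak_bins)
  if (gap < 1L || gap > k - 1L) {
    stop_ethopeak(sprintf("gap must be between 1 and %d", k - 1L),
                  "validation_error")
  }
  p1 <- peaks$peak_bins[gap]
  p2 <- peaks$peak_bins[gap + 1L]
  if (p2 - p1 < 2L) {
    stop_ethopeak(
      sprintf("peaks at bins %d and %d are adjacent: no interior bin", p1, p2),
      "degenerate_gap_error")
  }
  interior <- (p1 + 1L):(p2 - 1L)
  minimum_bin <- interior[which.min(hist$counts[interior])]
  structure(
    list(threshold = hist$bin_left_edges[minimum_bin] + hist$bin_width,
         gap = gap,
         minimum_bin = minimum_bin,
         histogram = hist,
         peaks = peaks),
    class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> %s threshold %g (interpeak minimum at bin %d, gap %d; peaks at bins %s)\n",
    x$histogram$metric_name, x$threshold, x$minimum_bin, x$gap,
    paste(x$peaks$peak_bins, collapse = ", ")))
  invisible(x)
}

#' Histogram, peak detection and interpeak minimum in one call
#'
#' @inheritParams metric_histogram
#' @inheritParams find_peaks
#' @inheritParams interpeak_minimum
#' @param ... Passed on to [find_peaks()].
#' @return A `threshold_result` (see [interpeak_minimum()]).
#' @export
#' @examples
#' x <- c(rnorm(500, 0.05, 0.01), rnorm(500, 0.6, 0.05))
#' threshold_from_values(x, bin_width = 0.02, expected_k = 2, gap = 1)
threshold_from_values <- function(data, metric = NULL, bin_width = NULL,
                                  expected_k = 2L, gap = 1L, range = NULL,
                                  ...) {
  h <- metric_histogram(data, metric = {{ metric }}, bin_width = bin_width,
                        range = range)
  interpeak_minimum(h, find_peaks(h, expected_k = expected_k, ...), gap = gap)
}
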