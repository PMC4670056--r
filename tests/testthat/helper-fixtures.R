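# shared fixture builders; everything is generated in code at test time

# a short constant-gravity series with optional heave sinusoid
make_accel <- function(seconds = 10, fs = 25, pitch_deg = 0,
                       osc_amp = 0, osc_freq = 0, noise_sd = 0, seed = 42) {
  set.seed(seed)
  n <- seconds * fs
  t <- (seq_len(n) - 1) / fs
  p <- pitch_deg * pi / 180
  accel_series(
    surge = sin(p) + rnorm(n, 0, noise_sd),
    sway = rnorm(n, 0, noise_sd),
    heave = cos(p) + osc_amp * sin(2 * pi * osc_freq * t) + rnorm(n, 0, noise_sd),
    sample_rate = fs
  )
}

# brute-force interior argmin between two peak bins (independent oracle)
oracle_interior_argmin <- function(counts, p1, p2) {
  interior <- (p1 + 1):(p2 - 1)
  interior[which.min(counts[interior])]
}

# build a metric_histogram directly from a count vector (unit bins at 0,1,...)
hist_from_counts <- function(counts, bin_width = 1) {
  values <- rep((seq_along(counts) - 0.5) * bin_width, times = counts)
  metric_histogram(values, bin_width = bin_width,
                   range = c(0, length(counts) * bin_width))
}

# peak set without running detection (for oracle tests)
peaks_at <- function(bins, expected_k = length(bins)) {
  structure(list(peak_bins = as.integer(sort(bins)),
                 expected_k = as.integer(expected_k), prominence = 0),
            class = "peak_set")
}

# check the land/water transition rule on a label vector
violates_transition_rule <- function(labels, anchor = "flight",
                                     a = "on_land", b = "on_water") {
  r <- rle(labels)
  v <- r$values
  any((v[-length(v)] == a & v[-1] == b) | (v[-length(v)] == b & v[-1] == a))
}
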