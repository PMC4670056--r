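test_that("binning is left-closed right-open and conserves counts", {
  h <- metric_histogram(c(0.01, 0.03, 0.03), bin_width = 0.02,
                        range = c(0, 0.06))
  expect_equal(h$counts, c(1, 2, 0))
  expect_equal(h$bin_left_edges, c(0, 0.02, 0.04))

  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(500, runif(1, -5, 5), runif(1, 0.1, 3))
    x[sample(500, 5)] <- NA
    h <- suppressMessages(metric_histogram(x, bin_width = 0.25))
    expect_equal(sum(h$counts), sum(is.finite(x)))
    expect_equal(diff(h$bin_left_edges),
                 rep(0.25, length(h$counts) - 1), tolerance = 1e-9)
  }
  expect_error(metric_histogram(c(NA_real_, NaN), bin_width = 1),
               class = "ethopeak_empty_input")
  expect_error(metric_histogram(1:3, bin_width = -1),
               class = "ethopeak_validation_error")
})

test_that("a boundary value falls in the bin whose left edge it is", {
  h <- metric_histogram(c(0.02), bin_width = 0.02, range = c(0, 0.06))
  expect_equal(h$counts, c(0, 1, 0))
})

test_that("peak detection finds the stated maxima and rejects monotone data", {
  h <- hist_from_counts(c(10, 4, 1, 6, 12))
  pk <- find_peaks(h, expected_k = 2, min_separation = 2)
  expect_equal(pk$peak_bins, c(1L, 5L))

  h2 <- hist_from_counts(c(10, 9, 8, 7))
  expect_error(find_peaks(h2, expected_k = 2),
               class = "ethopeak_modality_error")
})

test_that("simulated bimodal and trimodal mixtures are recovered", {
  set.seed(12)
  x <- c(rnorm(5000, 0.05, 0.015), rnorm(5000, 0.6, 0.06))
  h <- metric_histogram(x, bin_width = 0.02)
  pk <- find_peaks(h, expected_k = 2)
  centers <- h$bin_left_edges[pk$peak_bins] + 0.01
  expect_lt(abs(centers[1] - 0.05), 0.05)
  expect_lt(abs(centers[2] - 0.6), 0.15)

  y <- c(rnorm(3000, 0.02, 0.008), rnorm(3000, 0.25, 0.03),
         rnorm(3000, 0.8, 0.08))
  h3 <- metric_histogram(y, bin_width = 0.02)
  pk3 <- find_peaks(h3, expected_k = 3)
  c3 <- h3$bin_left_edges[pk3$peak_bins] + 0.01
  expect_lt(abs(c3[1] - 0.02), 0.04)
  expect_lt(abs(c3[2] - 0.25), 0.09)
  expect_lt(abs(c3[3] - 0.8), 0.2)
})

test_that("interpeak minimum takes the lowest interior bin, ties downward", {
  h <- hist_from_counts(c(10, 4, 1, 6, 12))
  res <- interpeak_minimum(h, peaks_at(c(1, 5)), gap = 1)
  expect_equal(res$minimum_bin, 3L)
  expect_equal(res$threshold, 3)   # right edge of unit bin 3

  h2 <- hist_from_counts(c(5, 2, 2, 5))
  res2 <- interpeak_minimum(h2, peaks_at(c(1, 4)), gap = 1)
  expect_equal(res2$minimum_bin, 2L)

  expect_error(interpeak_minimum(h, peaks_at(c(1, 2)), gap = 1),
               class = "ethopeak_degenerate_gap_error")
  expect_error(interpeak_minimum(h, peaks_at(c(1, 5)), gap = 2),
               class = "ethopeak_validation_error")
})

test_that("interpeak minimum equals brute-force interior argmin", {
  set.seed(13)
  for (i in 1:1000) {
    len <- sample(4:12, 1)
    counts <- sample(0:3, len, replace = TRUE)
    counts[1] <- counts[1] + 1          # non-degenerate ends
    counts[len] <- counts[len] + 1
    h <- hist_from_counts(counts)
    p1 <- 1L
    p2 <- len
    res <- interpeak_minimum(h, peaks_at(c(p1, p2)), gap = 1)
    expect_identical(res$minimum_bin, oracle_interior_argmin(counts, p1, p2))
  }
})

test_that("the threshold depends on histogram shape, not on total count", {
  set.seed(14)
  x <- c(rnorm(400, 0.05, 0.01), rnorm(400, 0.6, 0.05))
  t1 <- threshold_from_values(x, bin_width = 0.02, expected_k = 2, gap = 1)
  t3 <- threshold_from_values(rep(x, 3), bin_width = 0.02, expected_k = 2,
                              gap = 1)
  expect_equal(t1$threshold, t3$threshold)
})

test_that("thresholds from simulated mixtures fall between the modes", {
  set.seed(15)
  x <- c(rnorm(500, 0.05, 0.01), rnorm(500, 0.6, 0.05))
  res <- threshold_from_values(x, bin_width = 0.02, expected_k = 2, gap = 1)
  # the threshold cleanly separates the two components
  expect_true(all(x[1:500] < res$threshold))
  expect_true(all(x[501:1000] >= res$threshold))

  expect_error(
    threshold_from_values(rnorm(1000, 0.3, 0.02), bin_width = 0.02,
                          expected_k = 2, gap = 1),
    class = "ethopeak_modality_error")

  y <- c(rnorm(800, 0.02, 0.008), rnorm(800, 0.25, 0.02),
         rnorm(800, 0.8, 0.06))
  res2 <- threshold_from_values(y, bin_width = 0.02, expected_k = 3, gap = 2)
  expect_gt(res2$threshold, 0.25)
  expect_lt(res2$threshold, 0.8)
})

test_that("two-mode separation holds across seeds at large n", {
  for (s in 1:20) {
    set.seed(100 + s)
    x <- c(rnorm(5000, 0.05, 0.01), rnorm(5000, 0.6, 0.05))
    res <- threshold_from_values(x, bin_width = 0.02, expected_k = 2, gap = 1)
    expect_gt(res$threshold, 0.05)
    expect_lt(res$threshold, 0.6)
  }
})

test_that("tidy and autoplot expose the histogram, peaks and threshold", {
  set.seed(16)
  x <- c(rnorm(300, 0.05, 0.01), rnorm(300, 0.6, 0.05))
  res <- threshold_from_values(x, bin_width = 0.02, expected_k = 2, gap = 1)
  td <- tidy(res)
  expect_equal(sum(td$is_peak), 2)
  expect_equal(sum(td$is_minimum), 1)
  expect_equal(sum(td$count), 600)
  g <- glance(res)
  expect_equal(g$threshold, res$threshold)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(res$histogram), "ggplot")
})
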