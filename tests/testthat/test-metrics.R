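test_that("moving mean and SD match hand values and handle edges by fill", {
  expect_equal(moving_stat(rep(0.5, 100), 25, "sd"), rep(0, 100))
  expect_equal(moving_stat(c(1, 2, 3, 4, 5), 5, "mean"), rep(3, 5))
  expect_equal(moving_stat(c(1, 2, 3, 4, 5), 5, "sd")[3], 1.5811388,
               tolerance = 1e-6)
  expect_error(moving_stat(1:10, 11, "mean"),
               class = "ethopeak_insufficient_data")
  # interior values agree with a direct windowed computation
  set.seed(1)
  x <- rnorm(60)
  m <- moving_stat(x, 7, "sd")
  for (i in c(4, 20, 57)) {
    expect_equal(m[i], sd(x[(i - 3):(i + 3)]), tolerance = 1e-12)
  }
  # edge fill: first half-window carries the first fully-defined value
  expect_equal(m[1], m[4])
  expect_equal(m[60], m[57])
})

test_that("pitch and roll recover canonical orientations", {
  expect_equal(pitch(0, 0, 1), 0)
  expect_equal(pitch(1, 0, 0), 90)
  expect_equal(pitch(0.5, 0, 0.8660), 30, tolerance = 1e-3)
  expect_equal(roll(0, 0, 1), 0)
  expect_equal(roll(0, 1, 0), 90)
  expect_equal(roll(0, 0.5, 0.8660), 30, tolerance = 1e-3)
  expect_warning(p0 <- pitch(0, 0, 0), "undefined")
  expect_equal(p0, 0)
})

test_that("pitch and roll are invariant under positive scaling", {
  set.seed(2)
  for (i in 1:50) {
    v <- rnorm(3)
    if (all(v == 0)) next
    s <- runif(1, 0.1, 10)
    expect_equal(pitch(s * v[1], s * v[2], s * v[3]),
                 pitch(v[1], v[2], v[3]), tolerance = 1e-12)
    expect_equal(roll(s * v[1], s * v[2], s * v[3]),
                 roll(v[1], v[2], v[3]), tolerance = 1e-12)
  }
})

test_that("static acceleration smoothing: fixed point, sinusoid, ramp", {
  expect_equal(static_acceleration(rep(0.37, 100), 25), rep(0.37, 100))
  # full-period average of a zero-mean sinusoid vanishes at interior points
  t <- (0:249) / 25
  x <- 0.8 * sin(2 * pi * 1 * t)   # period 25 samples = window
  sm <- static_acceleration(x, 25)
  expect_lt(max(abs(sm[30:220])), 1e-6)
  # a centered mean preserves a linear ramp in the interior
  r <- seq(0, 1, length.out = 100)
  smr <- static_acceleration(r, 25)
  expect_equal(smr[20:80], r[20:80], tolerance = 1e-12)
})

test_that("dynamic body acceleration, ODBA and VeDBA match closed forms", {
  expect_equal(dynamic_body_acceleration(c(1, 2), c(0.5, 1)), c(0.5, 1))
  expect_error(dynamic_body_acceleration(1:3, 1:2),
               class = "ethopeak_alignment_error")
  expect_equal(odba(0.3, 0.4, 0), 0.7)
  expect_equal(vedba(0.3, 0.4, 0), 0.5)
  expect_equal(odba(0, 0, 0), 0)
  expect_equal(vedba(0, 0, 0), 0)
  expect_equal(odba(0.1, 0.1, 0.1), 0.3)
  expect_equal(vedba(0.1, 0.1, 0.1), 0.17321, tolerance = 1e-4)
})

test_that("compute_metrics on constant gravity gives still posture", {
  acc <- make_accel(seconds = 60, fs = 25)
  m <- compute_metrics(acc)
  expect_equal(nrow(m), 60)
  expect_equal(m$sd_heave, rep(0, 60))
  expect_equal(m$pitch, rep(0, 60))
  expect_equal(m$odba, rep(0, 60), tolerance = 1e-12)
})

test_that("compute_metrics recovers the RMS of a heave sinusoid", {
  acc <- make_accel(seconds = 60, fs = 25, osc_amp = 0.5, osc_freq = 5)
  m <- compute_metrics(acc)
  expect_equal(nrow(m), 60)
  interior <- 5:55
  # sample (n-1) SD of a full-period sinusoid: A/sqrt(2) * sqrt(n/(n-1))
  expect_equal(mean(m$sd_heave[interior]), 0.5 / sqrt(2) * sqrt(25 / 24),
               tolerance = 0.02)
})

test_that("per-sample DBA bounds hold: vedba <= odba <= sqrt(3) vedba", {
  acc <- make_accel(seconds = 30, fs = 25, osc_amp = 0.4, osc_freq = 3,
                    noise_sd = 0.1)
  m <- compute_metrics(acc)
  expect_true(all(m$vedba <= m$odba + 1e-12))
  expect_true(all(m$odba <= sqrt(3) * m$vedba + 1e-12))
  expect_true(all(m$sd_surge >= 0 & m$sd_sway >= 0 & m$sd_heave >= 0))
  expect_true(all(abs(m$pitch) <= 90 & abs(m$roll) <= 90))
})

test_that("a constant axis offset moves the mean but not sd, odba or vedba", {
  acc <- make_accel(seconds = 30, fs = 25, osc_amp = 0.3, osc_freq = 4,
                    noise_sd = 0.05, seed = 9)
  shifted <- acc
  shifted$heave <- shifted$heave + 0.25
  m1 <- compute_metrics(acc)
  m2 <- compute_metrics(shifted)
  interior <- 3:28
  expect_equal(m2$mean_heave[interior], m1$mean_heave[interior] + 0.25,
               tolerance = 1e-9)
  expect_equal(m2$sd_heave[interior], m1$sd_heave[interior], tolerance = 1e-6)
  expect_equal(m2$odba[interior], m1$odba[interior], tolerance = 1e-6)
  expect_equal(m2$vedba[interior], m1$vedba[interior], tolerance = 1e-6)
})

test_that("centered (odd) windows give time-reversal symmetric statistics", {
  set.seed(3)
  x <- rnorm(200)
  for (st in c("mean", "sd")) {
    expect_equal(moving_stat(rev(x), 25, st), rev(moving_stat(x, 25, st)),
                 tolerance = 1e-12)
  }
})

test_that("too-short input and metric CSV round-trip behave as documented", {
  acc <- make_accel(seconds = 1, fs = 25)
  expect_error(compute_metrics(acc), class = "ethopeak_insufficient_data")

  m <- compute_metrics(make_accel(seconds = 20, fs = 25, osc_amp = 0.2,
                                  osc_freq = 2, noise_sd = 0.02))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(m, path)
  back <- read_metrics_csv(path)
  expect_lt(max(abs(back$sd_heave - m$sd_heave)), 1e-6)
  expect_equal(names(back), names(m))
})
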