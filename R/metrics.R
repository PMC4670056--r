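#' Centered moving mean or standard deviation
#'
#' Rolling statistic over a centered window of exactly `window` samples,
#' aligned to the input grid. The standard deviation uses the sample (n-1)
#' denominator. Positions whose full window would fall outside the series
#' carry the nearest fully-defined value, so the output has the same length
#' as the input and stays aligned with raw time.
#'
#' @param x Numeric vector.
#' @param window Window length in samples (>= 2, <= `length(x)`).
#' @param stat `"mean"` or `"sd"`.
#' @return Numeric vector of `length(x)`.
#' @export
#' @examples
#' moving_stat(c(1, 2, 3, 4, 5), window = 5, stat = "mean")
moving_stat <- function(x, window, stat = c("mean", "sd")) {
  stat <- match.arg(stat)
  window <- as.integer(window)
  n <- length(x)
  if (window < 2L) {
    stop_ethopeak("window must be at least 2 samples", "validation_error")
  }
  if (window > n) {
    stop_ethopeak(
      sprintf("window (%d) exceeds series length (%d)", window, n),
      "insufficient_data")
  }
  # right-aligned rolling sums from data.table, then shifted to center
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  mu_right <- data.table::frollmean(x, n = window, align = "right")
  # defined centers are 1+half_lo .. n-half_hi; edges clamp to the nearest
  center_idx <- pmin(pmax(seq_len(n) + half_hi, window), n)
  out_mu <- mu_right[center_idx]
  if (stat == "mean") return(out_mu)
  s2_right <- data.table::frollsum(x * x, n = window, align = "right")
  s2 <- s2_right[center_idx]
  v <- (s2 - window * out_mu^2) / (window - 1)
  sqrt(pmax(v, 0))
}

#' Body pitch and roll from a tri-axial acceleration vector
#'
#' Orientation angles of the device (and hence the animal) relative to
#' gravity, in degrees:
#' pitch = arctan(surge / sqrt(sway^2 + heave^2)) * 180/pi and
#' roll = arctan(sway / sqrt(surge^2 + heave^2)) * 180/pi.
#' Both are invariant under positive scaling of the vector. An all-zero
#' vector has no defined orientation; it yields 0 with a warning.
#'
#' @param surge,sway,heave Acceleration components (g), vectorized.
#' @return Angle(s) in degrees, in \[-90, 90\].
#' @export
#' @examples
#' pitch(0, 0, 1)      # gravity on the heave axis: 0 degrees
#' pitch(1, 0, 0)      # gravity on the surge axis: 90 degrees
pitch <- function(surge, sway, heave) {
  angle_deg(surge, sqrt(sway^2 + heave^2), surge, sway, heave)
}

#' @rdname pitch
#' @export
roll <- function(surge, sway, heave) {
  angle_deg(sway, sqrt(surge^2 + heave^2), surge, sway, heave)
}

angle_deg <- function(num, den, surge, sway, heave) {
  zero <- surge == 0 & sway == 0 & heave == 0
  if (any(zero)) {
    warn(sprintf(
      "%d all-zero acceleration vector(s): orientation undefined, angle set to 0",
      sum(zero)))
  }
  out <- ifelse(den > 0, atan(num / den), sign(num) * pi / 2) * 180 / pi
  out[zero] <- 0
  out
}

#' Static (gravity-dominated) component of one axis
#'
#' Smooths an axis with a centered moving mean spanning one second of
#' samples, isolating the low-frequency, posture-encoding component.
#'
#' @param x Numeric vector (g).
#' @param window Smoothing window in samples (normally `round(sample_rate)`).
#' @return Numeric vector of `length(x)`.
#' @export
static_acceleration <- function(x, window) {
  moving_stat(x, window, stat = "mean")
}

#' Dynamic body acceleration and its summaries
#'
#' The dynamic component of an axis is raw minus static acceleration,
#' per sample. ODBA sums the absolute dynamic components of the three axes;
#' VeDBA is their Euclidean norm. For any sample,
#' `vedba <= odba <= sqrt(3) * vedba`.
#'
#' @param raw,static Numeric vectors of equal length (g).
#' @param dx,dy,dz Dynamic components of surge, sway and heave (g).
#' @return Numeric vector (g).
#' @export
#' @examples
#' odba(0.3, 0.4, 0)   # 0.7
#' vedba(0.3, 0.4, 0)  # 0.5
dynamic_body_acceleration <- function(raw, static) {
  if (length(raw) != length(static)) {
    stop_ethopeak(
      sprintf("raw (%d) and static (%d) series differ in length",
              length(raw), length(static)),
      "alignment_error")
  }
  raw - static
}

#' @rdname dynamic_body_acceleration
#' @export
odba <- function(dx, dy, dz) abs(dx) + abs(dy) + abs(dz)

#' @rdname dynamic_body_acceleration
#' @export
vedba <- function(dx, dy, dz) sqrt(dx^2 + dy^2 + dz^2)

#' Compute the ten per-second metrics from a raw acceleration series
#'
#' For each axis: moving mean and moving standard deviation over a one-second
#' window of samples (25 points at 25 Hz). Pitch and roll come by default
#' from the static (smoothed) components, reflecting posture rather than
#' per-sample jitter. ODBA and VeDBA summarize the dynamic components.
#' All quantities are computed as centered rolling values at every sample
#' and then taken at each whole-second tick, giving one row per second of
#' input; `mode = "block"` instead computes each statistic over
#' non-overlapping one-second blocks.
#'
#' @param accel Acceleration tibble from [accel_series()] / [read_accel_csv()].
#' @param sample_rate Hz; defaults to the series' `sample_rate` attribute.
#' @param mode `"rolling"` (default) or `"block"`.
#' @param angles `"static"` (default: pitch/roll from smoothed components) or
#'   `"raw"` (from raw samples).
#' @return A tibble with one row per whole second and columns `t`,
#'   `mean_surge`, `mean_sway`, `mean_heave`, `sd_surge`, `sd_sway`,
#'   `sd_heave`, `pitch`, `roll`, `odba`, `vedba`.
#' @export
compute_metrics <- function(accel, sample_rate = NULL,
                            mode = c("rolling", "block"),
                            angles = c("static", "raw")) {
  mode <- match.arg(mode)
  angles <- match.arg(angles)
  sample_rate <- sample_rate %||% attr(accel, "sample_rate")
  if (is.null(sample_rate)) {
    stop_ethopeak("sample_rate not supplied and not stored on the series",
                  "validation_error")
  }
  fs <- as.integer(round(sample_rate))
  n <- nrow(accel)
  if (n < 2L * fs) {
    stop_ethopeak(
      sprintf("need at least 2 s of data (%d samples); got %d", 2L * fs, n),
      "insufficient_data")
  }
  n_sec <- n %/% fs
  t0 <- attr(accel, "t0") %||% accel$time[1]

  ax <- list(surge = accel$surge, sway = accel$sway, heave = accel$heave)
  stat_ax <- lapply(ax, static_acceleration, window = fs)
  dyn <- Map(dynamic_body_acceleration, ax, stat_ax)
  ang_src <- if (angles == "static") stat_ax else ax

  if (mode == "rolling") {
    tick <- (seq_len(n_sec) - 1L) * fs + 1L
    take <- function(v) v[tick]
    mean_ax <- lapply(ax, function(v) take(moving_stat(v, fs, "mean")))
    sd_ax <- lapply(ax, function(v) take(moving_stat(v, fs, "sd")))
    pit <- take(pitch(ang_src$surge, ang_src$sway, ang_src$heave))
    rol <- take(roll(ang_src$surge, ang_src$sway, ang_src$heave))
    od <- take(odba(dyn$surge, dyn$sway, dyn$heave))
    ve <- take(vedba(dyn$surge, dyn$sway, dyn$heave))
  } else {
    blk <- rep(seq_len(n_sec), each = fs)
    used <- seq_len(n_sec * fs)
    per_block <- function(v, f) as.numeric(tapply(v[used], blk, f))
    mean_ax <- lapply(ax, per_block, f = mean)
    sd_ax <- lapply(ax, per_block, f = sd)
    pit <- per_block(pitch(ang_src$surge, ang_src$sway, ang_src$heave), mean)
    rol <- per_block(roll(ang_src$surge, ang_src$sway, ang_src$heave), mean)
    od <- per_block(odba(dyn$surge, dyn$sway, dyn$heave), mean)
    ve <- per_block(vedba(dyn$surge, dyn$sway, dyn$heave), mean)
  }

  tibble(
    t = t0 + seq_len(n_sec) - 1,
    mean_surge = mean_ax$surge, mean_sway = mean_ax$sway,
    mean_heave = mean_ax$heave,
    sd_surge = sd_ax$surge, sd_sway = sd_ax$sway, sd_heave = sd_ax$heave,
    pitch = pit, roll = rol, odba = od, vedba = ve
  )
}
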