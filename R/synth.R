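#' Statistical model of one behavior for the synthetic generator
#'
#' Each behavior is emulated by the features the classifier consumes, not by
#' biomechanical realism: a base body orientation (gravity rotated into the
#' device frame), bout-level and second-level posture variation, an optional
#' sinusoidal oscillation on the heave axis (wingbeats, footfalls), white
#' measurement noise per axis, and an immersion state for the wet/dry
#' logger.
#'
#' @param name Behavior label.
#' @param pitch,roll Base orientation in degrees.
#' @param pitch_jitter_sd SD (degrees) of a posture offset drawn once per
#'   bout — posture is a bout-level property, which is what makes posture
#'   histograms show tight per-behavior modes.
#' @param pitch_wander_sd SD (degrees) of additional per-second posture
#'   wander within a bout.
#' @param osc_amplitude Heave oscillation amplitude (g, >= 0).
#' @param osc_frequency Oscillation frequency (Hz; must be below the Nyquist
#'   frequency when the amplitude is positive).
#' @param noise_sd Gaussian measurement noise SD per axis (g).
#' @param immersion `"none"`, `"wet"` or `"dry"` — drives the simulated
#'   salt-water immersion logger.
#' @return A `behavior_model` list.
#' @export
behavior_model <- function(name, pitch = 0, roll = 0,
                           pitch_jitter_sd = 0, pitch_wander_sd = 0,
                           osc_amplitude = 0, osc_frequency = 0,
                           noise_sd = 0,
                           immersion = c("none", "wet", "dry")) {
  immersion <- match.arg(immersion)
  if (osc_amplitude < 0 || noise_sd < 0) {
    stop_ethopeak("osc_amplitude and noise_sd must be non-negative",
                  "validation_error")
  }
  structure(list(name = name, pitch = pitch, roll = roll,
                 pitch_jitter_sd = pitch_jitter_sd,
                 pitch_wander_sd = pitch_wander_sd,
                 osc_amplitude = osc_amplitude,
                 osc_frequency = osc_frequency,
                 noise_sd = noise_sd, immersion = immersion),
            class = "behavior_model")
}

#' Specification for a synthetic accelerometry recording
#'
#' @param schedule Data frame with columns `behavior` and `duration`
#'   (whole seconds >= 1), in recording order.
#' @param models Named list of [behavior_model()]s covering every scheduled
#'   behavior.
#' @param sample_rate Hz.
#' @param seed Integer seed; the same spec always generates bit-identical
#'   output.
#' @param transition_blur Seconds of linear crossfade inserted at each bout
#'   boundary (default 0 = instantaneous transitions). Blurred seconds keep
#'   the incoming bout's truth label; they exist to stress-test edge
#'   handling.
#' @param epoch_seconds Immersion logger epoch (default 600 s).
#' @param t0 Start time (seconds).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(schedule, models, sample_rate = 25, seed = 1,
                       transition_blur = 0, epoch_seconds = 600, t0 = 0) {
  schedule <- as_tibble(schedule)
  if (!all(c("behavior", "duration") %in% names(schedule))) {
    stop_ethopeak("schedule needs columns 'behavior' and 'duration'",
                  "validation_error")
  }
  if (any(schedule$duration < 1 | schedule$duration != round(schedule$duration))) {
    stop_ethopeak("schedule durations must be whole seconds >= 1",
                  "validation_error")
  }
  missing <- setdiff(unique(schedule$behavior), names(models))
  if (length(missing) > 0) {
    stop_ethopeak(
      sprintf("no behavior model for scheduled behavior(s): %s",
              paste(missing, collapse = ", ")),
      "validation_error")
  }
  nyq <- sample_rate / 2
  for (m in models) {
    if (m$osc_amplitude > 0 &&
        (m$osc_frequency <= 0 || m$osc_frequency >= nyq)) {
      stop_ethopeak(
        sprintf("model '%s': osc_frequency must be in (0, %g) Hz",
                m$name, nyq),
        "validation_error")
    }
  }
  structure(list(schedule = schedule, models = models,
                 sample_rate = sample_rate, seed = as.integer(seed),
                 transition_blur = transition_blur,
                 epoch_seconds = epoch_seconds, t0 = t0),
            class = "synth_spec")
}

#' Generate a labeled synthetic recording
#'
#' Per scheduled second the acceleration is gravity rotated by the
#' behavior's orientation (with per-bout jitter and per-second wander), plus
#' a heave-axis sinusoid, plus independent Gaussian noise per axis. Truth
#' labels are emitted at 1 Hz; if any model declares an immersion state, a
#' co-registered immersion series is produced with one value per full
#' epoch, `round(200 * wet fraction)`.
#'
#' @param spec A [synth_spec()].
#' @return List with `accel` (tibble as from [accel_series()]), `truth`
#'   (label tibble), and `immersion` (tibble or `NULL`).
#' @export
generate_accel <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  fs <- spec$sample_rate
  sched <- spec$schedule
  n_bouts <- nrow(sched)
  total_sec <- sum(sched$duration)
  n <- total_sec * fs

  # per-sample model parameters, assembled bout by bout
  deg2rad <- pi / 180
  gx <- gy <- gz <- amp <- phase <- noise <- numeric(n)
  pos <- 0L
  t_global <- (seq_len(n) - 1) / fs
  for (b in seq_len(n_bouts)) {
    m <- spec$models[[sched$behavior[b]]]
    dur <- sched$duration[b]
    nb <- dur * fs
    idx <- pos + seq_len(nb)
    p_bout <- m$pitch + rnorm(1, 0, m$pitch_jitter_sd)
    p_sec <- p_bout + rnorm(dur, 0, m$pitch_wander_sd)
    p <- rep(p_sec, each = fs) * deg2rad
    r <- m$roll * deg2rad
    gx[idx] <- sin(p)
    gy[idx] <- cos(p) * sin(r)
    gz[idx] <- cos(p) * cos(r)
    amp[idx] <- m$osc_amplitude
    phase[idx] <- 2 * pi * m$osc_frequency * t_global[idx]
    noise[idx] <- m$noise_sd
    pos <- pos + nb
  }

  # optional linear crossfade of the deterministic signal at bout boundaries
  blur <- spec$transition_blur
  if (blur > 0 && n_bouts > 1) {
    bounds <- cumsum(sched$duration * fs)[-n_bouts]
    nb <- as.integer(round(blur * fs))
    for (c0 in bounds) {
      k <- seq_len(min(nb, n - c0))
      w <- k / (nb + 1)
      prev <- c0                      # last sample of outgoing bout
      gx[c0 + k] <- (1 - w) * gx[prev] + w * gx[c0 + k]
      gy[c0 + k] <- (1 - w) * gy[prev] + w * gy[c0 + k]
      gz[c0 + k] <- (1 - w) * gz[prev] + w * gz[c0 + k]
      amp[c0 + k] <- (1 - w) * amp[prev] + w * amp[c0 + k]
    }
  }

  heave_osc <- amp * sin(phase)
  accel <- accel_series(
    surge = gx + rnorm(n, 0, 1) * noise,
    sway  = gy + rnorm(n, 0, 1) * noise,
    heave = gz + heave_osc + rnorm(n, 0, 1) * noise,
    sample_rate = fs, t0 = spec$t0
  )

  truth_labels <- rep(sched$behavior, times = sched$duration)
  truth <- label_series(truth_labels, t0 = spec$t0,
                        vocabulary = unique(c(sched$behavior, "unassigned")))

  states <- vapply(spec$models, function(m) m$immersion, character(1))
  immersion <- NULL
  if (any(states != "none")) {
    wet_sec <- rep(states[sched$behavior] == "wet", times = sched$duration)
    ep <- spec$epoch_seconds
    n_ep <- total_sec %/% ep
    if (n_ep > 0) {
      frac <- vapply(seq_len(n_ep), function(e) {
        mean(wet_sec[((e - 1) * ep + 1):(e * ep)])
      }, numeric(1))
      immersion <- tibble(time = spec$t0 + seq_len(n_ep) * ep,
                          value = as.integer(round(200 * frac)))
      attr(immersion, "epoch_seconds") <- ep
    }
  }
  list(accel = accel, truth = truth, immersion = immersion)
}

#' Default synthetic kittiwake deployment
#'
#' A two-hour recording at 25 Hz alternating on-land, flight and on-water
#' bouts, parameterized so the classifier's working assumptions hold the way
#' they do in real kittiwake data: strong 5-Hz heave oscillation in flight
#' (SD_Heave bimodal, modes separated by far more than their widths),
#' distinct land (~25 deg) and water (~5 deg) pitch modes whose per-second
#' distributions overlap in the tails (second-to-second posture wander) —
#' the situation that motivates the bout-averaging constraint — with flight
#' pitch in between and more variable, and a wet immersion state only on
#' water.
#' Bout durations are drawn from the seed: flight 60-240 s, land 240-720 s,
#' water 180-600 s.
#'
#' @param seed Integer seed (drives both the bout schedule and the noise).
#' @param transition_blur Passed to [synth_spec()].
#' @return A `synth_spec`.
#' @export
default_kittiwake_spec <- function(seed = 1, transition_blur = 0) {
  set.seed(seed)
  total <- 7200
  behaviors <- character(0)
  durations <- integer(0)
  ground <- "on_land"
  repeat {
    if (sum(durations) >= total) break
    behaviors <- c(behaviors, ground)
    durations <- c(durations, as.integer(round(
      if (ground == "on_land") runif(1, 240, 720) else runif(1, 180, 600))))
    if (sum(durations) >= total) break
    behaviors <- c(behaviors, "flight")
    durations <- c(durations, as.integer(round(runif(1, 60, 240))))
    ground <- if (ground == "on_land") "on_water" else "on_land"
  }
  over <- sum(durations) - total
  durations[length(durations)] <- durations[length(durations)] - over
  if (durations[length(durations)] < 1) {
    behaviors <- behaviors[-length(behaviors)]
    durations <- durations[-length(durations)]
  }
  models <- list(
    flight = behavior_model("flight", pitch = 12, pitch_jitter_sd = 4,
                            pitch_wander_sd = 1,
                            osc_amplitude = 0.5, osc_frequency = 5,
                            noise_sd = 0.05, immersion = "dry"),
    on_land = behavior_model("on_land", pitch = 25, pitch_jitter_sd = 2,
                             pitch_wander_sd = 5, noise_sd = 0.03,
                             immersion = "dry"),
    on_water = behavior_model("on_water", pitch = 5, pitch_jitter_sd = 2,
                              pitch_wander_sd = 5, noise_sd = 0.04,
                              immersion = "wet")
  )
  synth_spec(tibble(behavior = behaviors, duration = durations),
             models, sample_rate = 25, seed = seed,
             transition_blur = transition_blur)
}

#' Default synthetic human deployment
#'
#' About five minutes each of sitting, walking and running at 25 Hz (the
#' protocol used for validating the method on humans), with heave
#' oscillation amplitude ordered sitting < walking < running so that
#' SD_Heave is trimodal with well-separated modes.
#'
#' @inheritParams default_kittiwake_spec
#' @return A `synth_spec`.
#' @export
default_human_spec <- function(seed = 1, transition_blur = 0) {
  models <- list(
    sitting = behavior_model("sitting", pitch = 15, pitch_jitter_sd = 2,
                             pitch_wander_sd = 1, noise_sd = 0.02),
    walking = behavior_model("walking", pitch = 8, pitch_jitter_sd = 2,
                             pitch_wander_sd = 1.5,
                             osc_amplitude = 0.3, osc_frequency = 2,
                             noise_sd = 0.04),
    running = behavior_model("running", pitch = 5, pitch_jitter_sd = 2,
                             pitch_wander_sd = 2,
                             osc_amplitude = 1.0, osc_frequency = 3,
                             noise_sd = 0.06)
  )
  synth_spec(
    tibble(behavior = c("sitting", "walking", "running"),
           duration = c(300L, 300L, 300L)),
    models, sample_rate = 25, seed = seed,
    transition_blur = transition_blur)
}

#' Read a synthetic-recording spec from YAML or JSON
#'
#' The config mirrors [synth_spec()]: top-level `sample_rate`, `seed`,
#' optional `transition_blur`/`epoch_seconds`/`t0`, a `schedule` list of
#' `{behavior, duration}` entries and a `models` mapping of behavior name to
#' [behavior_model()] fields.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` spec file.
#' @return A `synth_spec`.
#' @export
read_synth_spec <- function(path) {
  if (!file.exists(path)) {
    stop_ethopeak(sprintf("spec file not found: %s", path), "format_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  schedule <- bind_rows(lapply(raw$schedule, function(e) {
    tibble(behavior = e$behavior, duration = e$duration)
  }))
  models <- lapply(names(raw$models), function(nm) {
    do.call(behavior_model, c(list(name = nm), raw$models[[nm]]))
  })
  names(models) <- names(raw$models)
  synth_spec(schedule, models,
             sample_rate = raw$sample_rate %||% 25,
             seed = raw$seed %||% 1,
             transition_blur = raw$transition_blur %||% 0,
             epoch_seconds = raw$epoch_seconds %||% 600,
             t0 = raw$t0 %||% 0)
}

#' Built-in classification plans for the two reference deployments
#'
#' `kittiwake_plan()`: flight is peeled off first from the bimodal SD_Heave
#' histogram (gap 1), then the remaining seconds are split into on-water /
#' on-land by pitch (threshold from the pitch histogram with flight
#' removed), with the bout-averaging constraint anchored on flight.
#' `human_plan()`: sitting is separated at the first interpeak minimum of
#' the trimodal SD_Heave histogram, then walking/running at the second
#' interpeak minimum of the same full histogram.
#'
#' @return A [classification_plan()].
#' @export
kittiwake_plan <- function() {
  classification_plan(
    vocabulary = c("flight", "nonflight", "on_land", "on_water"),
    steps = list(
      classification_step("sd_heave", expected_k = 2, gap = 1,
                          below = "nonflight", above = "flight",
                          bin_width = 0.02),
      classification_step("pitch", expected_k = 2, gap = 1,
                          below = "on_water", above = "on_land",
                          applies_to = "nonflight", bin_width = 1,
                          bout_constraint = bout_constraint("flight"))
    ))
}

#' @rdname kittiwake_plan
#' @export
human_plan <- function() {
  classification_plan(
    vocabulary = c("sitting", "moving", "walking", "running"),
    steps = list(
      classification_step("sd_heave", expected_k = 3, gap = 1,
                          below = "sitting", above = "moving",
                          bin_width = 0.02),
      classification_step("sd_heave", expected_k = 3, gap = 2,
                          below = "walking", above = "running",
                          applies_to = "moving", bin_width = 0.02,
                          histogram_scope = "all")
    ))
}
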