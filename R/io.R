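#' Construct a tri-axial acceleration series
#'
#' Bundles the three body-frame acceleration axes (surge = anterior-posterior,
#' sway = lateral, heave = dorso-ventral) into a per-sample tibble with a
#' known, uniform sampling rate. Values are in units of g throughout; no
#' conversion to m/s^2 is ever performed.
#'
#' @param surge,sway,heave Numeric vectors of equal length (acceleration, g).
#' @param sample_rate Sampling frequency in Hz (> 0).
#' @param t0 Timestamp of the first sample (seconds, arbitrary epoch).
#' @param device_range Absolute device recording limit in g; samples beyond
#'   it raise a warning but are kept (loggers clip rather than drop).
#'
#' @return A tibble with columns `time`, `surge`, `sway`, `heave` and
#'   attributes `sample_rate` and `t0`.
#' @export
#' @examples
#' accel_series(surge = c(0, 0), sway = c(0, 0), heave = c(1, 1), sample_rate = 25)
accel_series <- function(surge, sway, heave, sample_rate, t0 = 0,
                         device_range = 8) {
  n <- length(surge)
  if (n < 1L) {
    stop_ethopeak("acceleration series must contain at least one sample",
                  "empty_input")
  }
  if (length(sway) != n || length(heave) != n) {
    stop_ethopeak(
      sprintf("axis lengths differ: surge %d, sway %d, heave %d",
              n, length(sway), length(heave)),
      "alignment_error")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop_ethopeak("sample_rate must be a single positive number (Hz)",
                  "validation_error")
  }
  vals <- c(surge, sway, heave)
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop_ethopeak("acceleration values must all be finite", "parse_error")
  }
  n_out <- sum(abs(vals) > device_range)
  if (n_out > 0L) {
    warn(sprintf("%d sample(s) exceed the +/-%g g device range; retained",
                 n_out, device_range))
  }
  out <- tibble(
    time  = t0 + (seq_len(n) - 1) / sample_rate,
    surge = as.numeric(surge),
    sway  = as.numeric(sway),
    heave = as.numeric(heave)
  )
  attr(out, "sample_rate") <- sample_rate
  attr(out, "t0") <- t0
  out
}

read_chr_csv <- function(path) {
  if (!file.exists(path)) {
    stop_ethopeak(sprintf("file not found: %s", path), "format_error")
  }
  df <- suppressWarnings(readr::read_csv(
    path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE))
  if (nrow(df) == 0L) {
    stop_ethopeak(sprintf("no data rows in %s", path), "empty_input")
  }
  df
}

parse_num_col <- function(df, col, path) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(x) & !is.na(df[[col]]))
  if (anyNA(df[[col]])) bad <- sort(unique(c(bad, which(is.na(df[[col]])))))
  if (length(bad) > 0L) {
    stop_ethopeak(
      sprintf("non-numeric value in column '%s' of %s at data row %d",
              col, path, bad[1]),
      "parse_error")
  }
  x
}

require_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_ethopeak(
      sprintf("column(s) %s not found in %s (present: %s)",
              paste0("'", missing, "'", collapse = ", "), path,
              paste(names(df), collapse = ", ")),
      "format_error")
  }
}

#' Read a raw accelerometer CSV
#'
#' Reads a comma-separated file with a header row and maps its columns onto
#' the body-frame axis roles. Rows are taken in file order; nothing is
#' resampled, reordered or imputed. The sampling rate is supplied by the
#' caller (it is a device setting, not something inferred from timestamps).
#'
#' @param path Path to the CSV file.
#' @param column_map Named character vector mapping roles to file columns,
#'   e.g. `c(surge = "ax", sway = "ay", heave = "az")`.
#' @param sample_rate Sampling frequency in Hz.
#' @param time_col Optional name of a timestamp column (seconds); if `NULL`
#'   timestamps are synthesized from `t0` and `sample_rate`.
#' @param t0 Start time used when `time_col` is absent.
#' @inheritParams accel_series
#'
#' @return An acceleration tibble as from [accel_series()].
#' @export
read_accel_csv <- function(path,
                           column_map = c(surge = "ax", sway = "ay", heave = "az"),
                           sample_rate = 25,
                           time_col = NULL, t0 = 0, device_range = 8) {
  roles <- c("surge", "sway", "heave")
  if (!all(roles %in% names(column_map))) {
    stop_ethopeak("column_map must name columns for surge, sway and heave",
                  "validation_error")
  }
  df <- read_chr_csv(path)
  require_cols(df, unname(column_map[roles]), path)
  if (!is.null(time_col)) {
    require_cols(df, time_col, path)
    t0 <- parse_num_col(df, time_col, path)[1]
  }
  accel_series(
    surge = parse_num_col(df, column_map[["surge"]], path),
    sway  = parse_num_col(df, column_map[["sway"]], path),
    heave = parse_num_col(df, column_map[["heave"]], path),
    sample_rate = sample_rate, t0 = t0, device_range = device_range
  )
}

#' Write an acceleration series to CSV
#'
#' Columns `time`, `ax`, `ay`, `az` (surge, sway, heave) at 6-decimal fixed
#' precision, one row per sample.
#'
#' @param accel Acceleration tibble from [accel_series()] or [read_accel_csv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(accel, path) {
  out <- data.frame(
    time = sprintf("%.6f", accel$time),
    ax = sprintf("%.6f", accel$surge),
    ay = sprintf("%.6f", accel$sway),
    az = sprintf("%.6f", accel$heave)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a salt-water immersion logger CSV
#'
#' The leg-mounted logger reports one integer in \[0, 200\] per epoch
#' (default 10 min), the proportion of the epoch spent immersed scaled to
#' 200. The file has two columns: `time` (epoch-end timestamp, seconds) and
#' `value`.
#'
#' @param path Path to the CSV file.
#' @param epoch_seconds Epoch duration in seconds (default 600).
#' @return A tibble with columns `time`, `value` and attribute
#'   `epoch_seconds`.
#' @export
read_immersion_csv <- function(path, epoch_seconds = 600) {
  df <- read_chr_csv(path)
  require_cols(df, c("time", "value"), path)
  value <- parse_num_col(df, "value", path)
  bad <- which(value < 0 | value > 200 | value != round(value))
  if (length(bad) > 0L) {
    stop_ethopeak(
      sprintf("immersion value out of range [0, 200] at data row %d: %g",
              bad[1], value[bad[1]]),
      "range_error")
  }
  out <- tibble(time = parse_num_col(df, "time", path),
                value = as.integer(value))
  attr(out, "epoch_seconds") <- epoch_seconds
  out
}

#' @rdname read_immersion_csv
#' @param immersion Immersion tibble as returned by [read_immersion_csv()].
#' @export
write_immersion_csv <- function(immersion, path) {
  readr::write_csv(
    data.frame(time = immersion$time, value = as.integer(immersion$value)),
    path, progress = FALSE)
  invisible(path)
}

#' Construct a per-second behavior label series
#'
#' @param labels Character vector of behavior names at 1-second resolution.
#' @param t0 Timestamp of the first label (seconds).
#' @param vocabulary Closed set of permitted behavior names; the reserved
#'   name `"unassigned"` is always permitted. `NULL` accepts any label.
#' @return A tibble with columns `time`, `label` and attribute `vocabulary`.
#' @export
label_series <- function(labels, t0 = 0, vocabulary = NULL) {
  labels <- as.character(labels)
  if (!is.null(vocabulary)) {
    vocabulary <- union(vocabulary, "unassigned")
    bad <- which(!labels %in% vocabulary)
    if (length(bad) > 0L) {
      stop_ethopeak(
        sprintf("label '%s' (first at position %d) is not in the vocabulary: %s",
                labels[bad[1]], bad[1], paste(vocabulary, collapse = ", ")),
        "vocabulary_error")
    }
  }
  out <- tibble(time = t0 + seq_along(labels) - 1, label = labels)
  attr(out, "vocabulary") <- vocabulary
  out
}

#' Read and write per-second behavior labels
#'
#' The CSV has one row per second with columns `time` and `label`. Reading
#' with a vocabulary rejects any label outside it (the reserved
#' `"unassigned"` is always allowed).
#'
#' @param path Path to the CSV file.
#' @param vocabulary Optional closed set of permitted behavior names.
#' @return [read_labels_csv()] returns a label tibble; [write_labels_csv()]
#'   returns `path` invisibly.
#' @export
read_labels_csv <- function(path, vocabulary = NULL) {
  df <- read_chr_csv(path)
  require_cols(df, c("time", "label"), path)
  lab <- label_series(df$label, vocabulary = vocabulary)
  lab$time <- parse_num_col(df, "time", path)
  lab
}

#' @rdname read_labels_csv
#' @param labels Label tibble (columns `time`, `label`).
#' @export
write_labels_csv <- function(labels, path) {
  readr::write_csv(data.frame(time = labels$time, label = labels$label),
                   path, progress = FALSE)
  invisible(path)
}

#' Export a per-second metric table to CSV
#'
#' Fixed column order (`t`, the six moving means/SDs, `pitch`, `roll`,
#' `odba`, `vedba`) at 6-decimal fixed precision.
#'
#' @param metrics Metric tibble from [compute_metrics()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  cols <- c("t", "mean_surge", "mean_sway", "mean_heave",
            "sd_surge", "sd_sway", "sd_heave", "pitch", "roll",
            "odba", "vedba")
  out <- as.data.frame(lapply(metrics[cols], function(x) sprintf("%.6f", x)))
  names(out) <- cols
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  df <- read_chr_csv(path)
  cols <- c("t", "mean_surge", "mean_sway", "mean_heave",
            "sd_surge", "sd_sway", "sd_heave", "pitch", "roll",
            "odba", "vedba")
  require_cols(df, cols, path)
  as_tibble(lapply(setNames(cols, cols), function(cl) parse_num_col(df, cl, path)))
}

#' Read a classification plan from YAML or JSON
#'
#' The config mirrors [classification_plan()]: a `vocabulary` list and an
#' ordered `steps` list, each step giving `metric`, `expected_k`, `gap`,
#' `below`, `above` and optionally `applies_to`, `bin_width`,
#' `histogram_scope` and a `bout_constraint` block (`anchor`, `aggregate`,
#' `min_bout_seconds`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` plan file.
#' @return A validated [classification_plan()].
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) {
    stop_ethopeak(sprintf("plan file not found: %s", path), "format_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$steps)) {
    stop_ethopeak("plan config must contain a 'steps' list", "validation_error")
  }
  steps <- lapply(raw$steps, function(s) {
    bc <- if (!is.null(s$bout_constraint)) {
      do.call(bout_constraint, c(
        list(anchor = s$bout_constraint$anchor),
        s$bout_constraint[intersect(names(s$bout_constraint),
                                    c("aggregate", "min_bout_seconds"))]))
    }
    classification_step(
      metric = s$metric,
      expected_k = s$expected_k,
      gap = s$gap,
      below = s$below,
      above = s$above,
      applies_to = s$applies_to %||% "unassigned",
      bin_width = s$bin_width,
      histogram_scope = s$histogram_scope %||% "eligible",
      bout_constraint = bc
    )
  })
  classification_plan(vocabulary = unlist(raw$vocabulary), steps = steps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
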