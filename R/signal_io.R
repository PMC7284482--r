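#' Default device-to-body axis mapping
#'
#' Maps device coordinate axes onto the body axes V (vertical, +up),
#' ML (mediolateral) and AP (anteroposterior) for a phone worn in a pocket at
#' the L3 lumbar level with the screen facing outward: device y points up the
#' trunk (V), device x across it (ML), device z out of the screen (AP).
#' Device conventions vary, so the mapping is configurable; a leading "-"
#' flips the sign of an axis (e.g. `c(V = "-z", ML = "x", AP = "y")`).
#'
#' @return Named character vector with elements `V`, `ML`, `AP`.
#' @export
default_axis_map <- function() c(V = "y", ML = "x", AP = "z")

validate_axis_map <- function(axis_map) {
  if (!is.character(axis_map) ||
      !setequal(names(axis_map), c("V", "ML", "AP"))) {
    abort_gait("`axis_map` must be a named character vector with names V, ML, AP",
               "gait_parameter_error")
  }
  bare <- sub("^-", "", axis_map)
  if (!setequal(bare, c("x", "y", "z"))) {
    abort_gait("`axis_map` must assign each of device axes x, y, z exactly once",
               "gait_parameter_error")
  }
  axis_map[c("V", "ML", "AP")]
}

#' Construct an acceleration recording
#'
#' Container for raw timestamped triaxial acceleration in device coordinates,
#' as logged by a waist-worn phone. Timestamps may be irregular (the sensor
#' delivers samples at "fastest" mode, around 40 Hz in practice).
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param ax,ay,az Acceleration along the device axes, m/s², same length as `t`.
#' @param task Walking condition: `"ST"` (single task), `"DT"` (cognitive dual
#'   task) or `"FW"` (fast walking). Metadata only; processing is identical.
#' @param subject_id Opaque subject identifier.
#' @param nominal_rate Nominal sampling rate in Hz (default 40).
#' @param axis_map Device-to-body axis mapping, see [default_axis_map()].
#' @return Object of class `accel_recording`.
#' @export
accel_recording <- function(t, ax, ay, az, task = c("ST", "DT", "FW"),
                            subject_id = NA_character_, nominal_rate = 40,
                            axis_map = default_axis_map()) {
  task <- match.arg(task)
  t <- as.numeric(t)
  n <- length(t)
  if (n < 2L) {
    abort_gait(sprintf("recording needs at least 2 samples, got %d", n),
               "gait_data_error")
  }
  for (nm in c("ax", "ay", "az")) {
    a <- get(nm)
    if (length(a) != n) {
      abort_gait(sprintf("`%s` has length %d, expected %d", nm, length(a), n),
                 "gait_data_error")
    }
    if (anyNA(a) || any(!is.finite(a))) {
      abort_gait(sprintf("`%s` contains NaN/Inf/NA samples (row %d)",
                         nm, which(!is.finite(a))[1L]),
                 "gait_data_error")
    }
  }
  if (anyNA(t) || any(!is.finite(t))) {
    abort_gait("timestamps contain NaN/Inf/NA", "gait_data_error")
  }
  bad <- which(diff(t) <= 0)
  if (length(bad)) {
    abort_gait(sprintf(
      "timestamps must be strictly increasing; first violation at row %d (t = %g after %g)",
      bad[1L] + 1L, t[bad[1L] + 1L], t[bad[1L]]
    ), "gait_data_error")
  }
  check_scalar(nominal_rate, "nominal_rate", lower = 0, open_lower = TRUE)
  structure(
    list(t = t, ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
         task = task, subject_id = subject_id, nominal_rate = nominal_rate,
         axis_map = validate_axis_map(axis_map)),
    class = "accel_recording"
  )
}

#' @export
print.accel_recording <- function(x, ...) {
  span <- diff(range(x$t))
  cat(sprintf(
    "<accel_recording> %d samples over %.2f s (~%.1f Hz), task %s, subject %s\n",
    length(x$t), span, (length(x$t) - 1) / span, x$task, x$subject_id
  ))
  invisible(x)
}

#' Read an acceleration recording from CSV
#'
#' Expects a UTF-8 CSV with header `t,ax,ay,az`; `t` in seconds, accelerations
#' in m/s². Timestamps are kept as read — no resampling happens here. Rows
#' with NaN/Inf and non-monotonic timestamps are rejected rather than imputed.
#'
#' @param source File path or connection.
#' @inheritParams accel_recording
#' @return An [accel_recording()].
#' @export
read_recording <- function(source, task = c("ST", "DT", "FW"),
                           axis_map = default_axis_map(),
                           subject_id = NA_character_, nominal_rate = 40) {
  task <- match.arg(task)
  df <- tryCatch(
    utils::read.csv(source, stringsAsFactors = FALSE),
    error = function(e) abort_gait(
      paste0("cannot parse CSV: ", conditionMessage(e)), "gait_format_error")
  )
  need <- c("t", "ax", "ay", "az")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_gait(sprintf("CSV is missing required column(s): %s (header must be t,ax,ay,az)",
                       paste(missing_cols, collapse = ", ")),
               "gait_format_error")
  }
  for (nm in need) {
    if (!is.numeric(df[[nm]])) {
      abort_gait(sprintf("column `%s` is not numeric", nm), "gait_format_error")
    }
  }
  accel_recording(df$t, df$ax, df$ay, df$az, task = task,
                  subject_id = subject_id, nominal_rate = nominal_rate,
                  axis_map = axis_map)
}

#' Construct a uniform body-frame signal
#'
#' @param fs Sampling rate, Hz.
#' @param v,ml,ap Vertical, mediolateral, anteroposterior acceleration (m/s²).
#' @param t0 Start time of the first sample in recording time, seconds.
#' @param detrended Whether the axes have been mean-removed.
#' @return Object of class `uniform_signal`.
#' @export
uniform_signal <- function(fs, v, ml, ap, t0 = 0, detrended = FALSE) {
  check_scalar(fs, "fs", lower = 0, open_lower = TRUE)
  n <- length(v)
  if (n < 2L || length(ml) != n || length(ap) != n) {
    abort_gait("axes must have equal length >= 2", "gait_data_error")
  }
  structure(
    list(fs = fs, v = as.numeric(v), ml = as.numeric(ml), ap = as.numeric(ap),
         t0 = t0, detrended = isTRUE(detrended)),
    class = "uniform_signal"
  )
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal> %d samples @ %g Hz, t0 = %g s, detrended = %s\n",
              length(x$v), x$fs, x$t0, x$detrended))
  invisible(x)
}

#' Resample a recording onto a uniform grid
#'
#' Linearly interpolates each device axis onto the grid `t[1] + k/fs` covering
#' the recorded span, then applies the axis map so the output axes are body
#' axes V/ML/AP. Linear interpolation is exact for affine signals and is ample
#' at 40 Hz for gait content below ~4 Hz.
#'
#' @param recording An [accel_recording()].
#' @param fs Target sampling rate, Hz (default the recording's nominal rate).
#' @return A [uniform_signal()].
#' @export
resample_uniform <- function(recording, fs = recording$nominal_rate) {
  stopifnot(inherits(recording, "accel_recording"))
  check_scalar(fs, "fs", lower = 0, open_lower = TRUE)
  t <- recording$t
  span <- t[length(t)] - t[1L]
  if (span < 2 / fs) {
    abort_gait(sprintf("recording spans %.4f s, need at least %.4f s (2/fs)",
                       span, 2 / fs),
               "gait_data_error")
  }
  grid <- t[1L] + seq(0L, floor(span * fs + 1e-9)) / fs
  dev <- lapply(c(x = "ax", y = "ay", z = "az"), function(nm) {
    stats::approx(t, recording[[nm]], xout = grid, method = "linear",
                  rule = 1)$y
  })
  body <- lapply(recording$axis_map, function(ax) {
    sgn <- if (startsWith(ax, "-")) -1 else 1
    sgn * dev[[sub("^-", "", ax)]]
  })
  uniform_signal(fs, v = body$V, ml = body$ML, ap = body$AP, t0 = t[1L],
                 detrended = FALSE)
}

#' Trim the analysis window
#'
#' Keeps the half-open window `[start, start + duration)` relative to the
#' signal start. The defaults implement the acquisition protocol of dropping
#' the first 5 s (gait initiation) and analysing the following 30 s; at 40 Hz
#' that is exactly 1200 samples. Output length is `round(duration * fs)`
#' (round-half-even) regardless of input length beyond the minimum.
#'
#' @param signal A [uniform_signal()].
#' @param start Window start, seconds (default 5).
#' @param duration Window length, seconds (default 30).
#' @return A [uniform_signal()] of exactly `round(duration * fs)` samples.
#' @export
trim_window <- function(signal, start = 5, duration = 30) {
  stopifnot(inherits(signal, "uniform_signal"))
  check_scalar(start, "start", lower = 0)
  check_scalar(duration, "duration", lower = 0, open_lower = TRUE)
  fs <- signal$fs
  n <- length(signal$v)
  n_out <- round(duration * fs)
  k0 <- ceiling(start * fs - 1e-9)
  if (k0 + n_out > n) {
    abort_gait(sprintf(
      "window needs %.2f s (%d samples) but signal has %.2f s (%d samples)",
      start + duration, k0 + n_out, (n - 1) / fs, n
    ), "gait_data_error")
  }
  idx <- seq.int(k0 + 1L, k0 + n_out)
  uniform_signal(fs, signal$v[idx], signal$ml[idx], signal$ap[idx],
                 t0 = signal$t0 + k0 / fs, detrended = signal$detrended)
}

#' Remove the static component from each axis
#'
#' Subtracts the per-axis mean over the window, removing gravity and any
#' constant sensor offset — adequate for 30 s of straight steady walking.
#' A 2nd-order Butterworth high-pass (zero-phase, default cutoff 0.1 Hz) is
#' available for recordings with slow drift. Idempotent for the mean method.
#'
#' @param signal A [uniform_signal()].
#' @param method `"mean"` (default) or `"highpass"`.
#' @param cutoff High-pass cutoff in Hz (only for `method = "highpass"`).
#' @return The detrended [uniform_signal()], with `detrended = TRUE`.
#' @export
detrend <- function(signal, method = c("mean", "highpass"), cutoff = 0.1) {
  stopifnot(inherits(signal, "uniform_signal"))
  method <- match.arg(method)
  f <- switch(method,
    mean = function(x) x - mean(x),
    highpass = {
      check_scalar(cutoff, "cutoff", lower = 0, upper = signal$fs / 2,
                   open_lower = TRUE, open_upper = TRUE)
      bf <- signal::butter(2, cutoff / (signal$fs / 2), type = "high")
      function(x) as.numeric(signal::filtfilt(bf, x - mean(x)))
    }
  )
  uniform_signal(signal$fs, f(signal$v), f(signal$ml), f(signal$ap),
                 t0 = signal$t0, detrended = TRUE)
}

# ---- gait report -----------------------------------------------------------

#' Construct a gait report
#'
#' The five reported gait-quality parameters (in the app's report order:
#' step frequency, step intensity as acceleration RMS, step regularity,
#' step symmetry, step variability) plus per-axis RMS, stride regularity,
#' detected step count and quality flags. Metrics are `NaN` when the
#' corresponding quality flag is raised.
#'
#' @param step_frequency Cadence in Hz.
#' @param rms_v,rms_ml,rms_ap Per-axis RMS of detrended acceleration, m/s².
#' @param rms_reported The single RMS scalar shown on the report page
#'   (vertical-axis RMS).
#' @param step_regularity,stride_regularity Autocorrelation coefficients at
#'   the step and stride lags, in `[-1, 1]`.
#' @param step_symmetry `min/max` ratio of the two regularity coefficients,
#'   in `[0, 1]`; 1 means perfectly symmetric left/right steps.
#' @param step_variability Coefficient of variation of step intervals, >= 0.
#' @param n_steps_detected Number of detected step events.
#' @param quality_flags Character vector, e.g. `"no_periodicity"`,
#'   `"insufficient_steps"`.
#' @param config Optional list of the configuration that produced the report
#'   (kept for provenance, serialized with the report).
#' @return Object of class `gait_report`.
#' @export
gait_report <- function(step_frequency, rms_v, rms_ml, rms_ap, rms_reported,
                        step_regularity, stride_regularity, step_symmetry,
                        step_variability, n_steps_detected = NA_integer_,
                        quality_flags = character(), config = NULL) {
  num1 <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L) {
      abort_gait(sprintf("`%s` must be a single number", name),
                 "gait_parameter_error")
    }
    as.numeric(x)
  }
  r <- list(
    step_frequency    = num1(step_frequency, "step_frequency"),
    rms_reported      = num1(rms_reported, "rms_reported"),
    step_regularity   = num1(step_regularity, "step_regularity"),
    step_symmetry     = num1(step_symmetry, "step_symmetry"),
    step_variability  = num1(step_variability, "step_variability"),
    stride_regularity = num1(stride_regularity, "stride_regularity"),
    rms_v  = num1(rms_v, "rms_v"),
    rms_ml = num1(rms_ml, "rms_ml"),
    rms_ap = num1(rms_ap, "rms_ap"),
    n_steps_detected = as.integer(n_steps_detected),
    quality_flags = as.character(quality_flags),
    config = config
  )
  ok <- function(x) is.finite(x)
  if (ok(r$step_symmetry) && (r$step_symmetry < 0 || r$step_symmetry > 1)) {
    abort_gait("step_symmetry must lie in [0, 1]", "gait_parameter_error")
  }
  if (ok(r$step_variability) && r$step_variability < 0) {
    abort_gait("step_variability must be >= 0", "gait_parameter_error")
  }
  structure(r, class = "gait_report")
}

#' @export
print.gait_report <- function(x, digits = 3, ...) {
  cat("<gait_report>\n")
  cat(sprintf("  step frequency    : %.*f Hz\n", digits, x$step_frequency))
  cat(sprintf("  step intensity RMS: %.*f m/s^2 (V %.3f, ML %.3f, AP %.3f)\n",
              digits, x$rms_reported, x$rms_v, x$rms_ml, x$rms_ap))
  cat(sprintf("  step regularity   : %.*f\n", digits, x$step_regularity))
  cat(sprintf("  step symmetry     : %.*f\n", digits, x$step_symmetry))
  cat(sprintf("  step variability  : %.*f (CV)\n", digits, x$step_variability))
  cat(sprintf("  steps detected    : %s\n", x$n_steps_detected))
  if (length(x$quality_flags)) {
    cat("  flags             :", paste(x$quality_flags, collapse = ", "), "\n")
  }
  invisible(x)
}

# jsonlite has no standard JSON encoding for NaN; encode as null and restore.
.report_fields <- c("step_frequency", "rms_reported", "step_regularity",
                    "step_symmetry", "step_variability", "stride_regularity",
                    "rms_v", "rms_ml", "rms_ap")

#' Write a gait report as JSON
#'
#' The five reported metrics come first, in the report-page order; `NaN`
#' metrics are encoded as `null`. Round-trips losslessly through
#' [read_report()].
#'
#' @param report A [gait_report()].
#' @param sink File path or connection.
#' @export
write_report <- function(report, sink) {
  stopifnot(inherits(report, "gait_report"))
  out <- lapply(unclass(report)[.report_fields], function(x) {
    if (is.finite(x)) x else NULL
  })
  out$n_steps_detected <- report$n_steps_detected
  out$quality_flags <- as.list(report$quality_flags)
  if (!is.null(report$config)) out$config <- report$config
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  writeLines(json, sink)
  invisible(report)
}

#' Read a gait report written by [write_report()]
#'
#' @param source File path or connection.
#' @return A [gait_report()].
#' @export
read_report <- function(source) {
  x <- jsonlite::fromJSON(source, simplifyVector = TRUE)
  get_num <- function(nm) if (is.null(x[[nm]])) NaN else as.numeric(x[[nm]])
  vals <- lapply(.report_fields, get_num)
  names(vals) <- .report_fields
  gait_report(
    step_frequency = vals$step_frequency, rms_v = vals$rms_v,
    rms_ml = vals$rms_ml, rms_ap = vals$rms_ap,
    rms_reported = vals$rms_reported,
    step_regularity = vals$step_regularity,
    stride_regularity = vals$stride_regularity,
    step_symmetry = vals$step_symmetry,
    step_variability = vals$step_variability,
    n_steps_detected = if (is.null(x$n_steps_detected)) NA_integer_
                       else x$n_steps_detected,
    quality_flags = as.character(unlist(x$quality_flags)),
    config = x$config
  )
}
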