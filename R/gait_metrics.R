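#' Cadence search band
#'
#' Frequency band searched for the step-rate peak of the autocorrelation.
#' The default 1.0–3.5 Hz brackets typical older-adult cadences (group means
#' around 1.85–2.18 Hz across dual-task, normal and fast walking) with margin.
#'
#' @param f_min,f_max Band edges in Hz.
#' @return Object of class `cadence_band`.
#' @export
cadence_band <- function(f_min = 1.0, f_max = 3.5) {
  check_scalar(f_min, "f_min", lower = 0, open_lower = TRUE)
  check_scalar(f_max, "f_max", lower = f_min, open_lower = TRUE)
  structure(list(f_min = f_min, f_max = f_max), class = "cadence_band")
}

#' Unbiased autocorrelation of a zero-mean signal
#'
#' Computes `A(tau) = sum(x[t] * x[t + tau]) / (N - tau)` for lags 0..`max_lag`
#' and normalizes by `A(0)`, so the coefficient at lag 0 is exactly 1. The
#' `1/(N - tau)` divisor (the "unbiased" estimator) compensates for the
#' shrinking overlap at long lags, which matters for the stride lag in a 30 s
#' window. Note the normalized coefficients may slightly exceed 1 in
#' magnitude at long lags; downstream users clamp to `[-1, 1]`.
#'
#' @param x Zero-mean numeric vector, length >= 4.
#' @param max_lag Maximum lag in samples, in `[1, floor(N/2)]`.
#' @param fs Sampling rate in Hz (metadata; used to interpret lags).
#' @return Object of class `gait_acf` with `lags` (0..max_lag), `coef`, `fs`.
#' @export
unbiased_autocorrelation <- function(x, max_lag, fs = NA_real_) {
  n <- length(x)
  if (n < 4L) abort_gait("signal must have at least 4 samples", "gait_data_error")
  if (!is_scalar_number(max_lag) || max_lag < 1 || max_lag > floor(n / 2)) {
    abort_gait(sprintf("`max_lag` must be in [1, %d], got %s",
                       floor(n / 2), format(max_lag)),
               "gait_parameter_error")
  }
  max_lag <- as.integer(max_lag)
  if (abs(mean(x)) > 1e-6 * max(stats::sd(x), .Machine$double.eps)) {
    abort_gait("`x` must be mean-removed (call detrend() first)",
               "gait_contract_error")
  }
  a0 <- sum(x * x) / n
  if (a0 == 0) {
    abort_gait("all-zero signal: autocorrelation normalization undefined",
               "gait_degenerate_error")
  }
  coefs <- c(1, vapply(seq_len(max_lag), function(tau) {
    sum(x[seq_len(n - tau)] * x[seq.int(tau + 1L, n)]) / (n - tau)
  }, numeric(1)) / a0)
  structure(
    list(lags = 0:max_lag, coef = coefs, fs = fs, estimator = "unbiased"),
    class = "gait_acf"
  )
}

#' @export
print.gait_acf <- function(x, ...) {
  cat(sprintf("<gait_acf> unbiased, lags 0..%d @ %g Hz\n",
              max(x$lags), x$fs))
  invisible(x)
}

# indices (into coef, 1-based) of strict local maxima
.local_maxima <- function(coef) {
  n <- length(coef)
  if (n < 3L) return(integer())
  which(coef[2:(n - 1)] > coef[1:(n - 2)] & coef[2:(n - 1)] > coef[3:n]) + 1L
}

# parabolic refinement of a peak at integer lag `l` (coef indexed by lag+1)
.refine_peak <- function(coef, l) {
  i <- l + 1L
  if (i <= 1L || i >= length(coef)) return(as.numeric(l))
  y1 <- coef[i - 1L]; y2 <- coef[i]; y3 <- coef[i + 1L]
  den <- y1 - 2 * y2 + y3
  if (den >= 0) return(as.numeric(l))
  l + 0.5 * (y1 - y3) / den
}

#' Locate the step and stride lags of an autocorrelation series
#'
#' Finds the lag of the first dominant autocorrelation peak whose frequency
#' `fs/lag` lies inside the cadence band — the step lag — and the highest
#' peak within ±25% of twice the step lag — the stride lag. "First dominant"
#' means the smallest such lag whose coefficient reaches at least
#' `subharmonic_ratio` of the highest in-band peak: in asymmetric gait the
#' stride-lag peak exceeds the step-lag peak, and for common cadences the
#' stride frequency (half the cadence) also falls inside the band, so taking
#' the single highest peak would halve the estimated cadence. Peak lags are
#' refined by parabolic interpolation of the three samples around each peak;
#' the coefficients `Ad1`/`Ad2` are taken at the integer peak lags and
#' clamped to `[-1, 1]`.
#'
#' Candidate peaks must reach `min_peak_coef`: in a 30 s window the
#' autocorrelation of aperiodic noise stays well below 0.2, while even
#' irregular walking keeps its step-lag coefficient far above it, so the
#' gate separates "no gait present" from "gait present".
#'
#' @param acf A `gait_acf` from [unbiased_autocorrelation()] (its `fs` must
#'   be set).
#' @param band A [cadence_band()].
#' @param subharmonic_ratio Dominance threshold in (0, 1]; default 0.5.
#' @param min_peak_coef Minimum coefficient for a credible cadence peak
#'   (default 0.12).
#' @return List with `step_lag`, `stride_lag` (refined, fractional samples),
#'   `step_lag_samples`, `stride_lag_samples` (integer peak lags), and the
#'   peak coefficients `Ad1` (step) and `Ad2` (stride).
#' @export
find_step_stride_lags <- function(acf, band = cadence_band(),
                                  subharmonic_ratio = 0.5,
                                  min_peak_coef = 0.12) {
  stopifnot(inherits(acf, "gait_acf"), inherits(band, "cadence_band"))
  fs <- acf$fs
  if (!is_scalar_number(fs)) {
    abort_gait("acf$fs must be set to locate cadence lags", "gait_parameter_error")
  }
  if (band$f_max >= fs / 2) {
    abort_gait("cadence band must lie below fs/2", "gait_parameter_error")
  }
  check_scalar(subharmonic_ratio, "subharmonic_ratio", lower = 0, upper = 1,
               open_lower = TRUE)
  coef <- acf$coef
  peaks <- .local_maxima(coef)            # indices into coef; lag = index - 1
  peak_lags <- peaks - 1L
  in_band <- peak_lags >= fs / band$f_max & peak_lags <= fs / band$f_min &
    coef[peaks] >= min_peak_coef
  if (!any(in_band)) {
    abort_gait(sprintf("no autocorrelation peak in cadence band [%g, %g] Hz",
                       band$f_min, band$f_max),
               "gait_no_periodicity_error")
  }
  cand <- peak_lags[in_band]
  cand_coef <- coef[peaks[in_band]]
  dominant <- cand_coef >= subharmonic_ratio * max(cand_coef)
  step_lag_i <- min(cand[dominant])
  ad1 <- coef[step_lag_i + 1L]

  lo <- 1.5 * step_lag_i
  hi <- 2.5 * step_lag_i
  in_win <- peak_lags >= lo & peak_lags <= hi
  if (!any(in_win)) {
    abort_gait("no stride-lag peak within ±25% of twice the step lag",
               "gait_no_periodicity_error")
  }
  win_lags <- peak_lags[in_win]
  win_coef <- coef[peaks[in_win]]
  best <- win_coef == max(win_coef)
  stride_lag_i <- min(win_lags[best])     # ties broken toward smaller lag
  ad2 <- coef[stride_lag_i + 1L]

  clamp <- function(x) max(-1, min(1, x))
  list(
    step_lag = .refine_peak(coef, step_lag_i),
    stride_lag = .refine_peak(coef, stride_lag_i),
    step_lag_samples = step_lag_i,
    stride_lag_samples = stride_lag_i,
    Ad1 = clamp(ad1),
    Ad2 = clamp(ad2)
  )
}

#' Cadence from the step lag
#'
#' @param step_lag Step lag in samples (may be fractional), >= 1.
#' @param fs Sampling rate, Hz.
#' @return Step frequency `fs / step_lag` in Hz.
#' @export
step_frequency <- function(step_lag, fs) {
  check_scalar(step_lag, "step_lag", lower = 1)
  check_scalar(fs, "fs", lower = 0, open_lower = TRUE)
  fs / step_lag
}

#' Acceleration RMS per body axis
#'
#' Root mean square of the detrended acceleration — the "step intensity" of
#' the report. The single reported scalar is the vertical-axis RMS (the app
#' graphs the vertical axis); per-axis values are all returned.
#'
#' @param signal A detrended [uniform_signal()].
#' @return List with `rms_v`, `rms_ml`, `rms_ap`, `rms_reported` (m/s²).
#' @export
rms_metrics <- function(signal) {
  stopifnot(inherits(signal, "uniform_signal"))
  if (!signal$detrended) {
    abort_gait("rms_metrics() requires a detrended signal", "gait_contract_error")
  }
  rms <- function(x) sqrt(mean(x^2))
  out <- list(rms_v = rms(signal$v), rms_ml = rms(signal$ml),
              rms_ap = rms(signal$ap))
  out$rms_reported <- out$rms_v
  out
}

#' Regularity and symmetry from the step- and stride-lag coefficients
#'
#' Step regularity is the autocorrelation coefficient at the step lag (Ad1):
#' how alike consecutive steps are. Stride regularity is the coefficient at
#' the stride lag (Ad2): how alike consecutive strides are. Step symmetry is
#' `min(|Ad1|, |Ad2|) / max(|Ad1|, |Ad2|)`, bounded in [0, 1] (defined as 0
#' when both are 0): asymmetric left/right steps depress Ad1 relative to Ad2.
#'
#' @param Ad1,Ad2 Autocorrelation coefficients in `[-1, 1]`.
#' @return List with `step_regularity`, `stride_regularity`, `step_symmetry`.
#' @export
regularity_symmetry <- function(Ad1, Ad2) {
  check_scalar(Ad1, "Ad1", lower = -1, upper = 1)
  check_scalar(Ad2, "Ad2", lower = -1, upper = 1)
  mx <- max(abs(Ad1), abs(Ad2))
  list(
    step_regularity = Ad1,
    stride_regularity = Ad2,
    step_symmetry = if (mx == 0) 0 else min(abs(Ad1), abs(Ad2)) / mx
  )
}

#' Construct a step-event series
#'
#' @param event_times Step event times in seconds, strictly increasing.
#' @return Object of class `step_events` with `event_times` and `intervals`
#'   (`diff(event_times)`).
#' @export
step_events <- function(event_times) {
  event_times <- as.numeric(event_times)
  if (length(event_times) < 2L || any(diff(event_times) <= 0)) {
    abort_gait("event times must be strictly increasing (>= 2 events)",
               "gait_data_error")
  }
  structure(list(event_times = event_times, intervals = diff(event_times)),
            class = "step_events")
}

#' Detect step events in the vertical acceleration
#'
#' Local maxima of the detrended vertical signal, kept if they reach
#' `height_frac` of the 95th percentile of the signal and separated by at
#' least `separation_frac` of the step lag; when two candidates are closer,
#' the higher one wins (ties toward the earlier sample). Event times are at
#' sample resolution.
#'
#' @param v Detrended vertical acceleration.
#' @param fs Sampling rate, Hz.
#' @param step_lag Step lag in samples (from [find_step_stride_lags()]).
#' @param separation_frac Minimum peak separation as a fraction of the step
#'   lag (default 0.6).
#' @param height_frac Minimum height as a fraction of the 95th percentile of
#'   `v` (default 0.3).
#' @return Object of class `step_events`: `event_times` (s, relative to the
#'   start of `v`) and `intervals` (s).
#' @export
detect_steps <- function(v, fs, step_lag, separation_frac = 0.6,
                         height_frac = 0.3) {
  check_scalar(fs, "fs", lower = 0, open_lower = TRUE)
  check_scalar(step_lag, "step_lag", lower = 1)
  min_sep <- separation_frac * step_lag
  height <- height_frac * stats::quantile(v, 0.95, names = FALSE)
  cand <- .local_maxima(v)
  cand <- cand[v[cand] >= height]
  # greedy selection by descending height, enforcing the separation
  keep <- logical(length(v))
  ord <- cand[order(-v[cand], cand)]
  taken <- integer()
  for (i in ord) {
    if (!length(taken) || all(abs(taken - i) >= min_sep)) {
      taken <- c(taken, i)
    }
  }
  taken <- sort(taken)
  if (length(taken) < 4L) {
    abort_gait(sprintf("only %d step events detected; need at least 4",
                       length(taken)),
               "gait_insufficient_steps_error")
  }
  step_events((taken - 1L) / fs)
}

#' @export
print.step_events <- function(x, ...) {
  cat(sprintf("<step_events> %d events, mean interval %.3f s\n",
              length(x$event_times), mean(x$intervals)))
  invisible(x)
}

#' Step-time variability (coefficient of variation)
#'
#' Standard deviation of the detected step intervals (n−1 denominator)
#' divided by their mean.
#'
#' @param events A [detect_steps()] result (needs >= 4 intervals).
#' @return Unitless CV >= 0.
#' @export
step_variability <- function(events) {
  stopifnot(inherits(events, "step_events"))
  iv <- events$intervals
  if (length(iv) < 4L) {
    abort_gait(sprintf("need at least 4 step intervals, got %d", length(iv)),
               "gait_insufficient_steps_error")
  }
  stats::sd(iv) / mean(iv)
}

#' Analysis configuration
#'
#' All tunable parameters of the gait pipeline, logged into every report for
#' provenance.
#'
#' @param fs Resampling rate, Hz.
#' @param window_start,window_duration Analysis window, seconds.
#' @param f_min,f_max Cadence search band, Hz.
#' @param subharmonic_ratio Step-peak dominance threshold (see
#'   [find_step_stride_lags()]).
#' @param min_peak_coef Minimum credible cadence-peak coefficient (see
#'   [find_step_stride_lags()]).
#' @param separation_frac,height_frac Step-detection thresholds (see
#'   [detect_steps()]).
#' @param max_lag_seconds Longest autocorrelation lag evaluated, seconds
#'   (must cover 2.5x the longest step period in the band; capped at half the
#'   window).
#' @param lowpass If `TRUE`, apply a zero-phase 2nd-order Butterworth
#'   low-pass before analysis (gait content sits below ~4 Hz; off by default
#'   at 40 Hz sampling).
#' @param lowpass_cutoff Low-pass cutoff, Hz.
#' @param detrend_method `"mean"` or `"highpass"`, see [detrend()].
#' @return Object of class `gait_config`.
#' @export
gait_config <- function(fs = 40, window_start = 5, window_duration = 30,
                        f_min = 1.0, f_max = 3.5, subharmonic_ratio = 0.5,
                        min_peak_coef = 0.12,
                        separation_frac = 0.6, height_frac = 0.3,
                        max_lag_seconds = 4, lowpass = FALSE,
                        lowpass_cutoff = 10,
                        detrend_method = c("mean", "highpass")) {
  structure(list(
    fs = fs, window_start = window_start, window_duration = window_duration,
    f_min = f_min, f_max = f_max, subharmonic_ratio = subharmonic_ratio,
    min_peak_coef = min_peak_coef,
    separation_frac = separation_frac, height_frac = height_frac,
    max_lag_seconds = max_lag_seconds, lowpass = isTRUE(lowpass),
    lowpass_cutoff = lowpass_cutoff,
    detrend_method = match.arg(detrend_method)
  ), class = "gait_config")
}

#' Full gait analysis of a recording
#'
#' Runs the whole pipeline: resample to a uniform rate, trim the analysis
#' window, detrend, unbiased autocorrelation of the vertical axis, step- and
#' stride-lag location, then the five report metrics. If the signal has no
#' cadence peak in the band the report carries `NaN` metrics and the
#' `"no_periodicity"` flag; if too few steps are detected, step variability
#' is `NaN` and `"insufficient_steps"` is flagged. The same input always
#' yields the same report.
#'
#' @param recording An [accel_recording()].
#' @param config A [gait_config()].
#' @return A [gait_report()].
#' @export
analyze_recording <- function(recording, config = gait_config()) {
  stopifnot(inherits(recording, "accel_recording"),
            inherits(config, "gait_config"))
  sig <- resample_uniform(recording, fs = config$fs)
  sig <- trim_window(sig, start = config$window_start,
                     duration = config$window_duration)
  if (config$lowpass) {
    bf <- signal::butter(2, config$lowpass_cutoff / (config$fs / 2),
                         type = "low")
    lp <- function(x) as.numeric(signal::filtfilt(bf, x))
    sig <- uniform_signal(sig$fs, lp(sig$v), lp(sig$ml), lp(sig$ap),
                          t0 = sig$t0, detrended = sig$detrended)
  }
  sig <- detrend(sig, method = config$detrend_method)
  rms <- rms_metrics(sig)
  flags <- character()
  n <- length(sig$v)
  max_lag <- min(floor(n / 2), round(config$max_lag_seconds * config$fs))

  nan_report <- function(flags) gait_report(
    step_frequency = NaN, rms_v = rms$rms_v, rms_ml = rms$rms_ml,
    rms_ap = rms$rms_ap, rms_reported = rms$rms_reported,
    step_regularity = NaN, stride_regularity = NaN, step_symmetry = NaN,
    step_variability = NaN, n_steps_detected = 0L, quality_flags = flags,
    config = unclass(config)
  )

  acf <- tryCatch(
    unbiased_autocorrelation(sig$v, max_lag = max_lag, fs = config$fs),
    gait_degenerate_error = function(e) NULL
  )
  if (is.null(acf)) return(nan_report("no_periodicity"))

  lags <- tryCatch(
    find_step_stride_lags(acf, cadence_band(config$f_min, config$f_max),
                          subharmonic_ratio = config$subharmonic_ratio,
                          min_peak_coef = config$min_peak_coef),
    gait_no_periodicity_error = function(e) NULL
  )
  if (is.null(lags)) return(nan_report("no_periodicity"))

  reg <- regularity_symmetry(lags$Ad1, lags$Ad2)
  f_step <- step_frequency(lags$step_lag, config$fs)

  events <- tryCatch(
    detect_steps(sig$v, config$fs, lags$step_lag_samples,
                 separation_frac = config$separation_frac,
                 height_frac = config$height_frac),
    gait_insufficient_steps_error = function(e) NULL
  )
  cv <- NaN
  n_steps <- 0L
  if (!is.null(events)) {
    n_steps <- length(events$event_times)
    cv <- tryCatch(step_variability(events),
                   gait_insufficient_steps_error = function(e) NaN)
  }
  if (!is.finite(cv)) flags <- c(flags, "insufficient_steps")

  gait_report(
    step_frequency = f_step,
    rms_v = rms$rms_v, rms_ml = rms$rms_ml, rms_ap = rms$rms_ap,
    rms_reported = rms$rms_reported,
    step_regularity = reg$step_regularity,
    stride_regularity = reg$stride_regularity,
    step_symmetry = reg$step_symmetry,
    step_variability = cv,
    n_steps_detected = n_steps,
    quality_flags = flags,
    config = unclass(config)
  )
}
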