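#' Specification for a synthetic waist-accelerometer walk
#'
#' Parameters of the simulated walking signal. Defaults emulate a typical
#' older-adult straight walk recorded at the lower back by a phone sampling
#' around 40 Hz: cadence 2.0 Hz, step-timing jitter CV 0.05, left/right
#' amplitude asymmetry 0.2, sensor noise 0.5 m/s², and slightly irregular
#' timestamps (SD 3 ms around the nominal grid).
#'
#' @param f_step Step frequency (cadence), Hz, in (0.5, 4).
#' @param duration Recording length, seconds (>= 35 to cover the default
#'   5–35 s analysis window; shorter values are allowed for callers that
#'   override the window).
#' @param fs_nominal Nominal sampling rate, Hz.
#' @param timestamp_jitter_sd SD of Gaussian timestamp jitter, seconds.
#' @param jitter_cv CV of step-interval timing jitter (>= 0).
#' @param delta Left/right step-amplitude asymmetry in [0, 0.9]: odd steps
#'   have amplitude `step_amp * (1 + delta)`, even steps `step_amp * (1 - delta)`.
#' @param noise_sd Additive Gaussian sensor noise SD, m/s².
#' @param step_amp Step-impulse amplitude, m/s².
#' @param seed Integer RNG seed.
#' @return Object of class `synthetic_gait_spec`.
#' @export
synthetic_gait_spec <- function(f_step = 2.0, duration = 40, fs_nominal = 40,
                                timestamp_jitter_sd = 0.003, jitter_cv = 0.05,
                                delta = 0.2, noise_sd = 0.5, step_amp = 3,
                                seed = 1L) {
  check_scalar(f_step, "f_step", lower = 0.5, upper = 4,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(duration, "duration", lower = 2 / f_step, open_lower = TRUE)
  check_scalar(fs_nominal, "fs_nominal", lower = 0, open_lower = TRUE)
  check_scalar(timestamp_jitter_sd, "timestamp_jitter_sd", lower = 0)
  check_scalar(jitter_cv, "jitter_cv", lower = 0)
  check_scalar(delta, "delta", lower = 0, upper = 0.9)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(step_amp, "step_amp", lower = 0, open_lower = TRUE)
  if (!is_scalar_number(seed)) {
    abort_gait("`seed` must be a single integer", "gait_parameter_error")
  }
  structure(list(
    f_step = f_step, duration = duration, fs_nominal = fs_nominal,
    timestamp_jitter_sd = timestamp_jitter_sd, jitter_cv = jitter_cv,
    delta = delta, noise_sd = noise_sd, step_amp = step_amp,
    seed = as.integer(seed)
  ), class = "synthetic_gait_spec")
}

# raised-cosine pulse of unit height and width w centred at 0
.raised_cosine <- function(t, w) {
  ifelse(abs(t) <= w / 2, 0.5 * (1 + cos(2 * pi * t / w)), 0)
}

#' Generate a synthetic walking recording with ground truth
#'
#' Step times are cumulative sums of intervals
#' `T_i = (1/f_step) * (1 + eps_i)` with `eps_i` i.i.d. Gaussian
#' `(0, jitter_cv^2)` clipped at ±3 SD (so intervals stay positive; the small
#' shrinkage of the realized CV is why the ground truth stores the CV
#' recomputed from the emitted step times, not the nominal one). The vertical
#' channel is a train of raised-cosine pulses of width `0.3 / f_step`, with
#' odd/even amplitudes `step_amp * (1 ± delta)` (left/right asymmetry), plus
#' gravity (9.81 m/s²) and sensor noise. The mediolateral channel is a
#' stride-periodic sinusoid (frequency `f_step / 2`, amplitude
#' `0.5 * delta * step_amp`) plus noise; the anteroposterior channel is noise
#' only. Timestamps are a uniform grid at `fs_nominal` with Gaussian jitter,
#' sorted and strictly increasing. Body axes map to device axes by the
#' inverse of [default_axis_map()] (V -> ay, ML -> ax, AP -> az). The same
#' seed gives bit-identical output.
#'
#' @param spec A [synthetic_gait_spec()].
#' @return List with `recording` (an [accel_recording()]) and `truth`
#'   (class `gait_ground_truth`: `f_step`, `true_interval_cv` — the realized
#'   CV — `delta`, `step_times`).
#' @export
generate_walk <- function(spec) {
  stopifnot(inherits(spec, "synthetic_gait_spec"))
  with_seed(spec$seed, {
    T0 <- 1 / spec$f_step
    n_steps_max <- ceiling(spec$duration * spec$f_step) + 10L
    eps <- stats::rnorm(n_steps_max, 0, spec$jitter_cv)
    eps <- pmin(pmax(eps, -3 * spec$jitter_cv), 3 * spec$jitter_cv)
    step_times <- cumsum(T0 * (1 + eps))
    step_times <- step_times[step_times <= spec$duration]

    n <- round(spec$duration * spec$fs_nominal) + 1L
    ts <- (seq_len(n) - 1L) / spec$fs_nominal
    if (spec$timestamp_jitter_sd > 0) {
      ts <- sort(ts + stats::rnorm(n, 0, spec$timestamp_jitter_sd))
      ts <- ts[c(TRUE, diff(ts) > 1e-9)]
    }
    n <- length(ts)

    w <- 0.3 / spec$f_step
    v <- rep(9.81, n)
    amp <- spec$step_amp *
      (1 + spec$delta * ifelse(seq_along(step_times) %% 2L == 1L, 1, -1))
    for (i in seq_along(step_times)) {
      s <- step_times[i]
      idx <- which(ts >= s - w / 2 & ts <= s + w / 2)
      if (length(idx)) {
        v[idx] <- v[idx] + amp[i] * .raised_cosine(ts[idx] - s, w)
      }
    }
    ml <- 0.5 * spec$delta * spec$step_amp *
      sin(pi * spec$f_step * ts)                 # stride frequency f_step/2
    ap <- numeric(n)
    if (spec$noise_sd > 0) {
      v <- v + stats::rnorm(n, 0, spec$noise_sd)
      ml <- ml + stats::rnorm(n, 0, spec$noise_sd)
      ap <- ap + stats::rnorm(n, 0, spec$noise_sd)
    }

    iv <- diff(step_times)
    truth <- structure(list(
      f_step = spec$f_step,
      true_interval_cv = if (length(iv) >= 2) stats::sd(iv) / mean(iv) else NA_real_,
      delta = spec$delta,
      step_times = step_times
    ), class = "gait_ground_truth")

    # body -> device per the default map: V = +y, ML = +x, AP = +z
    rec <- accel_recording(
      t = ts, ax = ml, ay = v, az = ap, task = "ST",
      subject_id = sprintf("sim-%d", spec$seed),
      nominal_rate = spec$fs_nominal, axis_map = default_axis_map()
    )
    list(recording = rec, truth = truth)
  })
}

#' @export
print.gait_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<gait_ground_truth> f_step %.3g Hz, %d steps, realized interval CV %.4f, delta %.2g\n",
    x$f_step, length(x$step_times), x$true_interval_cv, x$delta
  ))
  invisible(x)
}

#' Generate a synthetic study cohort
#'
#' Emulates the 2 (region, between) x 3 (age group, between) x 3 (task,
#' within) mixed design of a smartphone gait study. Each metric value is
#' `grand_mean + region effect + age effect + task effect + subject random
#' intercept + residual`; the subject intercept makes the data genuinely
#' repeated-measures, so the sphericity machinery downstream is exercised.
#' Factor levels are synthetic stand-ins ("Beijing-like"/"Chongqing-like",
#' "60-69"/"70-79"/"80-89", "ST"/"DT"/"FW").
#'
#' @param n_per_cell Subjects per region x age cell (>= 2).
#' @param grand_mean Grand mean of the metric.
#' @param region_effects,age_effects,task_effects Named numeric additive
#'   shifts per level (defaults all zero).
#' @param subject_sd SD of the subject random intercept.
#' @param noise_sd Residual SD.
#' @param metric Metric name stored in the table.
#' @param seed Integer RNG seed.
#' @return Long-format `data.frame` with columns `subject_id`, `region`,
#'   `age_group`, `task`, `metric`, `value`; one row per subject x task.
#' @export
generate_cohort <- function(n_per_cell, grand_mean = 2.0,
                            region_effects = c("Beijing-like" = 0, "Chongqing-like" = 0),
                            age_effects = c("60-69" = 0, "70-79" = 0, "80-89" = 0),
                            task_effects = c(ST = 0, DT = 0, FW = 0),
                            subject_sd = 0.15, noise_sd = 0.1,
                            metric = "step_frequency", seed = 1L) {
  if (!is_scalar_number(n_per_cell) || n_per_cell < 2) {
    abort_gait("`n_per_cell` must be at least 2", "gait_parameter_error")
  }
  n_per_cell <- as.integer(n_per_cell)
  regions <- names(region_effects)
  ages <- names(age_effects)
  tasks <- names(task_effects)
  if (length(regions) != 2L || length(ages) != 3L || length(tasks) != 3L) {
    abort_gait("design must be 2 regions x 3 age groups x 3 tasks",
               "gait_parameter_error")
  }
  check_scalar(subject_sd, "subject_sd", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  with_seed(seed, {
    cells <- expand.grid(region = regions, age_group = ages,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    subj <- cells[rep(seq_len(nrow(cells)), each = n_per_cell), ]
    n_subj <- nrow(subj)
    subj$subject_id <- sprintf("S%03d", seq_len(n_subj))
    subj$intercept <- stats::rnorm(n_subj, 0, subject_sd)
    long <- subj[rep(seq_len(n_subj), each = length(tasks)), ]
    long$task <- rep(tasks, times = n_subj)
    long$value <- grand_mean +
      region_effects[long$region] + age_effects[long$age_group] +
      task_effects[long$task] + long$intercept +
      stats::rnorm(nrow(long), 0, noise_sd)
    out <- data.frame(
      subject_id = long$subject_id, region = long$region,
      age_group = long$age_group, task = long$task,
      metric = metric, value = as.numeric(long$value),
      stringsAsFactors = FALSE, row.names = NULL
    )
    out
  })
}

#' Generate synthetic Likert survey responses
#'
#' Draws `n` respondents x `n_items` items from per-item categorical response
#' distributions over the 5-point scale.
#'
#' @param n Number of respondents (0 allowed: empty table).
#' @param response_model Either a probability vector of length 5 (recycled
#'   across items) or an `n_items` x 5 matrix of per-item probabilities; each
#'   row must sum to 1.
#' @param n_items Number of items (default 10, the SUS layout).
#' @param seed Integer RNG seed.
#' @return `data.frame` with columns `item1..item<n_items>`, values 1–5.
#' @export
generate_survey <- function(n, response_model = rep(0.2, 5), n_items = 10L,
                            seed = 1L) {
  if (!is_scalar_number(n) || n < 0) {
    abort_gait("`n` must be a non-negative count", "gait_parameter_error")
  }
  n <- as.integer(n)
  n_items <- as.integer(n_items)
  if (is.vector(response_model)) {
    response_model <- matrix(response_model, nrow = n_items, ncol = 5,
                             byrow = TRUE)
  }
  if (!is.matrix(response_model) || nrow(response_model) != n_items ||
      ncol(response_model) != 5L ||
      any(response_model < 0) ||
      any(abs(rowSums(response_model) - 1) > 1e-8)) {
    abort_gait("`response_model` must be n_items x 5 probabilities summing to 1 per item",
               "gait_parameter_error")
  }
  with_seed(seed, {
    out <- as.data.frame(matrix(NA_integer_, nrow = n, ncol = n_items))
    names(out) <- paste0("item", seq_len(n_items))
    if (n > 0) {
      for (j in seq_len(n_items)) {
        out[[j]] <- sample.int(5L, n, replace = TRUE, prob = response_model[j, ])
      }
    }
    out
  })
}
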