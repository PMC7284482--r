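---
title: "Trunk-accelerometry gait metrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trunk-accelerometry gait metrics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitacc)
```

This vignette is the package's own account of its methods: the signal model
behind the five gait parameters, the statistical machinery for cohort
evaluation, the parameters a user may want to move, and the places where the
design was genuinely open and a choice had to be made.

## The acquisition model

A phone worn in a pocket at the L3 lumbar level approximates the body's
centre of mass, so its vertical acceleration carries one impulse per step.
The sensor delivers samples "as fast as possible", which in practice means
an irregular stream at roughly 40 Hz. The protocol is 35 s of straight
walking; the first 5 s (gait initiation) are discarded and seconds 5–35 are
analysed — the half-open window `[5, 35)`, exactly
`round(30 × 40) = 1200` samples at the 40 Hz analysis rate.

The pipeline in `analyze_recording()` is:

1. `resample_uniform()` — linear interpolation of each device axis onto the
   grid `t[1] + k/fs`, then the device→body axis map. Linear interpolation
   is exact for affine signals, and at 40 Hz its error for sub-4 Hz gait
   content is far below the sensor noise floor; higher-order schemes add
   nothing here.
2. `trim_window()` — the `[5, 35)` s window; the output length is defined as
   `round(duration × fs)` (round-half-even) so it never depends on how much
   extra signal was recorded.
3. `detrend()` — per-axis mean subtraction. Over 30 s of steady straight
   walking the static component is gravity plus sensor offset, and a mean
   is the most transparent estimate of it. A zero-phase 2nd-order
   Butterworth high-pass (default cutoff 0.1 Hz) is available for recordings
   with slow drift, but is off by default: it changes nothing for compliant
   recordings and complicates the RMS interpretation.
4. Unbiased autocorrelation of the vertical axis, peak location, and the
   five metrics.

Readers reject NaN/Inf samples and non-monotone timestamps as data errors
rather than imputing: a gait report silently computed over repaired data is
worse than no report.

## The five parameters

**Unbiased autocorrelation.** For the zero-mean vertical signal `x` of
length `N`,

\[
A(\tau) = \frac{1}{N-\tau} \sum_{t=1}^{N-\tau} x(t)\,x(t+\tau),
\qquad a(\tau) = A(\tau)/A(0).
\]

The `1/(N−τ)` divisor removes the triangular bias of the naive estimator,
which matters at the stride lag in a 30 s window (a biased estimator would
shrink stride regularity by `τ/N` ≈ 3–7% and distort the symmetry ratio).
The price is that `a(τ)` may slightly exceed 1 in magnitude at long lags;
coefficients used as regularity values are clamped to `[-1, 1]`.

**Step and stride lags.** Walking is near-periodic at two scales: the step
(one heel strike to the next, either foot) and the stride (two steps, same
foot). With left/right asymmetry the signal is strictly periodic only at
the stride, so the stride-lag peak `Ad2` can *exceed* the step-lag peak
`Ad1`. This creates a sub-harmonic ambiguity: for cadences around 2 Hz the
stride frequency (~1 Hz) also lies inside any reasonable cadence search
band, and simply taking the highest in-band peak would halve the estimated
cadence precisely for asymmetric walkers. `find_step_stride_lags()`
therefore takes the *smallest* lag among in-band local maxima whose
coefficient reaches at least `subharmonic_ratio` (default 0.5) of the
highest in-band peak. The factor 0.5 sits midway between the two regimes:
even strongly asymmetric gait (δ = 0.4) keeps `Ad1/Ad2` above ~0.6, while
spurious noise peaks in a 1200-sample window stay an order of magnitude
below a genuine cadence peak.

Two further numerical choices:

* Candidate peaks must reach `min_peak_coef` (default 0.12). The in-band
  autocorrelation of aperiodic noise in a 1200-sample window stays below
  ~0.1 (the coefficient standard error is ≈ `1/√(N−τ)` ≈ 0.03), while any
  detectable walking keeps its cadence peak well above 0.17. The gate is
  what turns "phone on a table" into a `no_periodicity` quality flag rather
  than a nonsense cadence.
* Peak lags are refined by parabolic interpolation through the three
  samples around the peak. Integer lags quantize cadence to `fs/k`; at
  2.4 Hz and 40 Hz the nearest integer lag alone leaves a ~0.05 Hz error,
  which is the entire error budget a cadence estimator should have. The
  refinement is exact for a locally quadratic peak and never moves the lag
  by more than half a sample. The integer peak lags are kept for the
  regularity coefficients and step detection.
* The stride lag is the highest local maximum within ±25% of twice the step
  lag; ties are broken toward the smaller lag (the higher cadence),
  deterministically.

**Step frequency** is `fs / step_lag` with the refined lag.

**RMS** is computed per body axis on the detrended window; the single
reported "step intensity" is the vertical RMS, because the vertical axis is
what the app displays and the published tables print one scalar. The other
axes remain in the report.

**Regularity and symmetry.** Step regularity = `Ad1`, stride regularity =
`Ad2`, step symmetry = `min(|Ad1|,|Ad2|)/max(|Ad1|,|Ad2|)` (0 if both are
0). The published value ranges cannot discriminate between this bounded
ratio and an unbounded `Ad1/Ad2`; the bounded form was chosen because it is
scale-free, lies in `[0, 1]` with 1 = perfect symmetry, and degrades
gracefully when either coefficient is small. Each metric sits behind its
own function, so an alternative definition is a one-function change.

**Step variability** is the coefficient of variation (n−1 standard
deviation over mean) of the intervals between detected step events.
Detection takes local maxima of the vertical signal with minimum separation
`0.6 × step_lag` and height at least `0.3 ×` the 95th percentile of the
window — both fractions configurable; the separation fraction must stay
above 0.5 (else both feet's peaks of one stride can merge) and below ~0.8
(else jittered steps get skipped). Event times are kept at sample
resolution; at 40 Hz the ±12.5 ms quantization adds ≈ 0.014 to the CV in
quadrature, which is visible but small against the 0.08–0.13 CVs typical of
older adults. An amplitude-based variability definition was the main
alternative; temporal CV was adopted as the standard frailty-linked
measure, and the choice is isolated in `step_variability()`.

The three walking conditions (single task, cognitive dual task, fast
walking) are metadata only: the computation is identical across tasks.

## The synthetic walking signal

`generate_walk()` is the package's ground-truth instrument, not a fixture:
step times are cumulative sums of intervals
`T_i = (1/f_step)(1 + ε_i)`, `ε_i ~ N(0, jitter_cv²)` clipped at ±3σ
(clipping rather than rejection keeps the draw count — and hence the seeded
stream — independent of the realization; the boundary mass is ≤ 0.3% at the
CVs used, and the ground truth stores the *realized* CV recomputed from the
emitted step times, so the truth is exact by construction). The vertical
channel is a train of raised-cosine pulses of width `0.3/f_step` with
odd/even amplitudes `step_amp(1 ± δ)` — smooth, band-limited, analytically
controlled, which is all an autocorrelation-based pipeline can see — plus
gravity and Gaussian noise. The mediolateral channel carries a
stride-frequency sinusoid proportional to δ, the anteroposterior channel
noise only, and timestamps get Gaussian jitter (SD 3 ms) before sorting, to
exercise the resampler.

Defaults are one realistic older-adult walk, chosen once: cadence 2.0 Hz
(the published single-task group mean is 1.99 Hz), timing jitter CV 0.05,
asymmetry δ = 0.2 (together these put regularity and symmetry in the
neighbourhood of the published group ranges, symmetry ≈ 0.9), noise SD
0.5 m/s² against 3 m/s² pulses, 40 s duration so the 35 s protocol fits.

What the simulator does *not* emulate — turning, stops, arm/phone slippage,
surface changes, waveform shape differences between individuals, and any
coupling between amplitude and timing — bounds what green tests mean:
recovery results validate the estimator chain on compliant straight-walk
signals, not robustness to protocol violations.

`generate_cohort()` builds the 2 (region) × 3 (age) between × 3 (task)
within design as `grand mean + factor shifts + subject random intercept +
residual`. The subject intercept is what makes the data genuinely
repeated-measures, so the sphericity machinery is exercised rather than
decorative. `generate_survey()` draws 5-point Likert items from per-item
categorical distributions.

## Cohort statistics

`mixed_rm_anova()` is a univariate split-plot ANOVA with two error strata:
subjects-within-groups for the between effects (region, age, their
interaction) and task×subjects-within-groups for the within effects (task
and its interactions). Sums of squares are Type III, computed by
model comparison on effect-coded design matrices; for balanced data this
coincides with the classical marginal-means decomposition (the test suite
checks every F against a literal cell-means oracle and against `car`'s
mixed-model table), and it remains well-defined for the unequal region
cells real studies have. Total SS is conserved across the partition on
balanced data to 1e-8.

Sphericity of the task factor is assessed with Mauchly's W on the pooled
within-cell covariance of the orthonormal task contrasts, with the standard
chi-square approximation. When `p < .05` (the conditional policy;
`always`/`never` overrides exist) the within-subject F tests use
Greenhouse–Geisser corrected degrees of freedom, `ε = (Σλ)²/((k−1)Σλ²)`
over the contrast-covariance eigenvalues, bounded in `[1/(k−1), 1]` — this
is what produces the non-integer df such studies print. Both numerator and
denominator df are reported (published tables often print only one).
Subjects with missing task rows are excluded listwise with a logged count;
a singular contrast covariance is a degenerate-data error, not a number.

`lsd_posthoc()` implements Fisher's LSD exactly as named: all pairwise t
tests using the error mean square and df of the factor's own stratum, with
**no multiplicity adjustment** — protection comes only from the preceding
omnibus F, which is LSD's defining (and often criticised) property. Users
wanting familywise control should adjust the returned p values themselves.
The confidence intervals in `cell_descriptives()` use t quantiles, not
normal ones, because the oldest age stratum of a realistic cohort is small.

`sus_score()` maps the 10 alternating-polarity items to
`2.5·(Σ_odd (s−1) + Σ_even (5−s))` ∈ [0, 100]; `likert_summary()` gives
mean (SD, n−1) per acceptance measure, optionally split by the app function
being rated.

## Problem sizes and tolerances in the test suite

The recovery and calibration tests run at the sizes the methods are meant
for: 50-seed sweeps of 40 s walks for cadence (mean absolute error ≤ 0.05
Hz across 1.6–2.4 Hz), variability recovery (mean CV within
[0.035, 0.065] at true 0.05 — the window is asymmetric around the truth
because sample-resolution event times add quantization variance), and the
monotonicity of regularity in jitter and symmetry in asymmetry; 1000
simulated null cohorts of 120 subjects for the task-test type-I rate
(accepted band 3–7% at α = .05). Exact identities (windowing, SUS anchors,
autocorrelation against the literal two-loop formula, ANOVA against the
cell-means oracle) are tested at 1e-8–1e-12. The noiseless symmetric walk
must come out with symmetry ≥ 0.95 and variability ≤ 0.01; at the default
noise and jitter these bounds do not hold and are not claimed — the
noiseless limit is the contract, the noisy sweeps are recovery statistics.

## Known limitations

* The device→body axis mapping is an assumption (configurable); a phone
  mounted differently needs a different `axis_map`.
* Step symmetry as a min/max coefficient ratio and variability as temporal
  CV are documented choices among established alternatives; both are
  isolated behind single functions.
* The pipeline assumes straight steady walking; it flags, but does not
  segment, recordings that violate this.
* Walking speed and step length are out of scope (they need distance or an
  inverted-pendulum model, which a single trunk accelerometer cannot supply
  alone).
* The ANOVA is univariate-with-correction by design, matching how such
  studies report; no multivariate tests are offered.
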