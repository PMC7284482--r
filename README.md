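# gaitacc

Gait-quality metrics from a waist-worn accelerometer, plus the statistics
used to evaluate smartphone gait monitoring in older adults.

## The problem

Stride-to-stride timing variability, gait regularity and left/right
symmetry are established markers of fall risk and frailty in older adults.
A smartphone worn in a pocket at the third lumbar vertebra (L3, close to the
body's centre of mass) records trunk acceleration at roughly 40 Hz while the
wearer walks straight for 35 seconds; after discarding the first 5 s of gait
initiation, the remaining 30 s are reduced to five gait-quality parameters:

| parameter | definition | units |
|---|---|---|
| step frequency | cadence, from the step-lag of the autocorrelation | Hz |
| step intensity (RMS) | root mean square of detrended vertical acceleration | m/s² |
| step regularity | autocorrelation coefficient at the step lag (Ad1) | – |
| step symmetry | min(|Ad1|, |Ad2|) / max(|Ad1|, |Ad2|) | – |
| step variability | CV of detected step intervals (sd/mean, n−1) | – |

The core statistic is the **unbiased autocorrelation** of the zero-mean
vertical acceleration *x*:

    A(τ) = [1 / (N − τ)] Σ_t x(t) x(t + τ),   normalized by A(0)

Its first dominant peak inside the 1.0–3.5 Hz cadence band gives the step
lag (coefficient Ad1, step regularity); the highest peak near twice that
lag gives the stride lag (Ad2, stride regularity). In asymmetric gait,
consecutive steps differ while consecutive strides stay alike, so Ad1 falls
relative to Ad2 and the min/max ratio drops below 1.

The package is for researchers in wearable-sensor gait analysis: it
implements the full recording-to-report pipeline, a synthetic
walking-signal generator with known ground truth for validation, and the
evaluation statistics for a 2 (region) × 3 (age group) × 3 (walking task)
mixed cohort design — split-plot repeated-measures ANOVA with Mauchly
sphericity testing and Greenhouse–Geisser correction, LSD post hoc
comparisons, System Usability Scale scoring and Likert summaries.

## Worked example

Simulate a 40 s walk (cadence 2.0 Hz, step-timing jitter CV 0.05,
left/right amplitude asymmetry 0.2, sensor noise 0.5 m/s²) and analyse it:

```r
library(gaitacc)
sim <- generate_walk(synthetic_gait_spec(f_step = 2.0, seed = 7))
sim$truth
#> <gait_ground_truth> f_step 2 Hz, 79 steps, realized interval CV 0.0464, delta 0.2
analyze_recording(sim$recording)
#> <gait_report>
#>   step frequency    : 1.968 Hz
#>   step intensity RMS: 1.000 m/s^2 (V 1.000, ML 0.462, AP 0.421)
#>   step regularity   : 0.628
#>   step symmetry     : 0.932
#>   step variability  : 0.053 (CV)
#>   steps detected    : 58
```

The report recovers the simulated cadence within 0.04 Hz, the timing CV
within 0.01, and the asymmetry depresses symmetry below 1.

Cohort statistics on a synthetic study (24 subjects per region × age cell,
task shifts DT −0.14 Hz and FW +0.19 Hz around a 1.99 Hz grand mean):

```r
coh <- generate_cohort(24, grand_mean = 1.99,
                       task_effects = c(ST = 0, DT = -0.14, FW = 0.19),
                       seed = 20)
mixed_rm_anova(coh)
#> Mixed repeated-measures ANOVA (144 subjects)
#> Mauchly W = 0.9842, p = 0.3361; GG epsilon = 0.9845
#>                   term        SS df_num df_den         F epsilon corrected        p
#>                 region 0.0186940      1    138   0.26375      NA     FALSE 6.08e-01
#>              age_group 0.1150800      2    138   0.81182      NA     FALSE 4.46e-01
#>       region:age_group 0.0045956      2    138   0.03242      NA     FALSE 9.68e-01
#>                   task 7.3607000      2    276 340.39000      NA     FALSE 3.12e-75
#>            task:region 0.0185310      2    276   0.85696      NA     FALSE 4.26e-01
#>         task:age_group 0.0195790      4    276   0.45271      NA     FALSE 7.70e-01
#>  task:region:age_group 0.0135530      4    276   0.31336      NA     FALSE 8.69e-01
```

Only the injected task effect is significant; sphericity holds, so no
correction is applied. `lsd_posthoc(coh, factor = "task")` then shows all
three pairwise task differences significant, with the dual task slowest and
fast walking fastest — the ordering such studies report.

A command-line wrapper with `analyze`, `simulate`, `cohort`, `anova` and
`sus` subcommands is installed at `inst/cli/gaitacc` (see `?gait_cli`).

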