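Package: gaitacc
Title: Gait Quality Metrics from a Waist-Worn Accelerometer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the five trunk-accelerometry gait-quality parameters
    (step frequency, acceleration root mean square, step regularity, step
    symmetry, and step variability) from timestamped triaxial acceleration
    recorded at the lower back (L3), using the unbiased autocorrelation of
    the vertical acceleration and step-event detection. Includes a synthetic
    walking-signal generator with known ground truth, and the evaluation
    statistics used in smartphone gait studies: mixed repeated-measures
    ANOVA with Mauchly sphericity test and Greenhouse-Geisser correction,
    LSD post hoc comparisons, System Usability Scale scoring, and Likert
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
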