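Package: addhrvr
Title: Simulation and Evaluation of Additional Heart Rate Variability
    Reduction Trigger Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting metabolically adjusted, transient decreases of
    heart rate variability (additional HRV reduction, AddHRVr) in minute-level
    ambulatory RMSSD and activity-energy-expenditure recordings. Implements
    per-participant calibration regressions of RMSSD on energy expenditure
    (linear and inverse variants) with outlier screening, static and dynamic
    (moving-buffer) k-out-of-n trigger algorithms with a refractory silent
    period, run-length detection of objective stress transitions under a
    minimum-episode rule, and a participant-level bootstrap of random-intercept
    logistic models that estimates the statistical power and odds change with
    which each of the 435 window-length by window-threshold algorithm settings
    predicts increases of objective stress. A seeded synthetic-cohort generator
    with known ground truth makes the full two-step pipeline testable without
    access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
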