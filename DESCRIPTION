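Package: mndaccel
Title: Wrist Accelerometry Outcomes and Trial Design in Motor Neuron Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating wrist-worn accelerometer outcomes as
    longitudinal endpoints in motor neuron disease. Extracts epoch-level
    features from raw tri-axial acceleration (ENMO, activity counts, MVPA,
    peak 5-h ENMO, 95th-percentile 6-min peak activity, step counts) with a
    7-day trim-and-average protocol; fits linear mixed-effects and joint
    longitudinal-survival models with a Weibull baseline hazard to estimate
    per-month decline and hazard ratios; estimates clinical-trial sample
    sizes by Schoenfeld event calculations and bootstrap resampling of
    slope-based trials; and provides descriptive association analyses
    (ALSFRS-R domain scoring, partial correlations with Holm correction,
    PCA on model residuals, Kaplan-Meier/log-rank comparisons). Includes a
    synthetic-data generator so the full pipeline can be exercised and
    tested without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    survival,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
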