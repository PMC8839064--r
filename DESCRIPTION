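Package: OAPredict
Title: Optimized Aggregation of Predictions for Cardiovascular
    Sufficiency Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Machine-learning assessment of cardiovascular sufficiency
    during fluid resuscitation from non-invasive vital signs.  Implements
    window-level featurization of physiological recordings (heart-rate
    variability, photo-plethysmography pulse geometry, beat-to-beat
    hemodynamics), per-subject personal-baseline normalization by stable-stage
    median and 90% range, and the Optimized Aggregation of Predictions
    framework, which replaces the unavailable personal baseline of a new
    patient with a majority vote over predictions obtained under previously
    seen subjects' normalization factors.  Includes a synthetic
    hemorrhage/resuscitation cohort simulator (waveform and feature-level
    tiers), nested leave-one-subject-out evaluation, ROC analysis with
    cost-optimal operating-point selection, Wilson intervals, and McNemar
    comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
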