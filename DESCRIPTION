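Package: gfrdm
Title: GFR Estimating Models for Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Development and validation tools for glomerular filtration rate
    (GFR) estimating models in type 2 diabetic cohorts: the published
    creatinine-based comparator equations (CKD-EPI and two Japanese
    equations), sex-specific two-slope log-spline regression equations,
    a three-layer back-propagation neural network with genetic-algorithm
    optimized initialization (GABP) and internal-validation model selection,
    linear calibration of renal dynamic imaging GFR to the dual plasma
    sample reference, and the standard clinical validation metrics (bias,
    interquartile-range precision, P30 accuracy) with bootstrap confidence
    intervals and paired significance tests. A synthetic diabetic cohort
    generator with a configurable ground-truth GFR model makes the whole
    development/validation pipeline exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
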