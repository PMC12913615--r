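Package: rtacc
Title: Reaction Time-Accuracy Correlation Digital Biomarkers from
    Computerized Cognitive Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the reaction time-accuracy correlation (RTACC), a
    per-participant digital biomarker that summarizes the coupling of speed
    and accuracy across game-based computerized cognitive training tasks,
    and relates it to cognitive outcome change with covariate-adjusted
    linear regression, Huber robust regression, recursive path analysis
    with blood biomarkers, and responder classification scored by ROC/AUC
    with bootstrap confidence intervals. Ships a calibrated synthetic-cohort
    generator that emulates a 24-week multi-domain intervention trial in
    older adults with mild cognitive impairment (adaptive task difficulty,
    a planted per-participant RT-accuracy coupling, and outcome and
    biomarker changes from planted linear effects), so the entire pipeline
    can be exercised and validated without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
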