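Package: calval
Title: Calibration Assessment and Updating of Clinical Risk Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate how well the risk estimates of a binary
    prediction model agree with observed event proportions, following the
    hierarchy of mean, weak, moderate and strong calibration. Provides the
    observed/expected ratio and calibration-in-the-large intercept, the
    logistic recalibration intercept and slope, flexible calibration curves
    with pointwise confidence bands (natural cubic spline or local linear
    regression), the concordance statistic, and the (discouraged)
    Hosmer-Lemeshow test. Miscalibrated models can be corrected by intercept
    updating, logistic recalibration or full refitting. A binormal cohort
    simulator with controlled prevalence, discrimination and linear-logit
    miscalibration makes every estimator verifiable by parameter recovery.
    Includes a command-line interface for assessment, simulation, updating
    and curve export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
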