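Package: evtpredict
Title: Ordinal Outcome and Thrombectomy Benefit Prediction Models for
    Anterior Circulation Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Development and validation of CT-feature-based
    proportional-odds models of 90-day functional outcome (modified
    Rankin Scale) and of individual benefit from endovascular
    thrombectomy in pooled multi-trial stroke cohorts. Provides
    restricted cubic spline design matrices, a maximum-likelihood
    cumulative-logit fitter with backward elimination and likelihood
    ratio tests, discrimination and calibration metrics (ordinal and
    binary C-statistics, calibration slope and intercept), matched-pair
    benefit metrics (C-for-benefit, mean benefit calibration),
    leave-one-study-out internal-external cross-validation with
    DerSimonian-Laird random-effects pooling, bootstrap model
    comparison, multiple imputation by chained equations, and a
    calibrated synthetic multi-trial cohort generator for end-to-end
    testing when patient-level trial data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    yaml,
    jsonlite
Suggests:
    MASS,
    optparse,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
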