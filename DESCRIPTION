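Package: gadating
Title: Gestational Age Dating Uncertainty and Preterm Birth Predictor
    Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how uncertainty in gestational age (GA)
    dating distorts the observed performance of spontaneous preterm birth
    (sPTB) risk predictors. Provides guideline-derived Gaussian error
    models for ultrasound and last-menstrual-period (LMP) dating,
    conditional error statistics for LMP dates confirmed by ultrasound,
    monotone spline interpolation of weekly GA-at-birth count tables to a
    daily sampling distribution, a perfect-predictor degradation
    simulation summarised as per-dating-group AUCs with an ROC confidence
    band, threshold-classifier performance statistics for case-control
    designs (sensitivity, specificity, prevalence-anchored PPV/NPV with
    case-control confidence intervals), expected outcome-label
    misclassification estimation, and a synthetic cohort generator with
    known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    pROC,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
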