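Package: telewalk
Title: Trend Analysis and Walking-Distance Prediction from Telehealth
    Monitoring of Peripheral Arterial Disease Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing home-monitoring data from patients with
    peripheral arterial disease enrolled in a structured walking-training
    program: a seeded synthetic cohort generator calibrated to published
    summary statistics (daily steps, pain scores, well-being, unsupervised
    6-minute walk tests), weekly aggregation and normalisation of
    patient-reported time series, adherence and correlation reports with a
    normality-gated choice between Pearson and Spearman, paired pre/post
    Wilcoxon comparisons, four predictors of the study-end 6-minute-walk
    distance (baseline carry-forward, cohort average improvement,
    individual and pooled logarithmic trend interpolation, and best-subset
    linear regression), and a leave-one-out evaluation harness producing
    RMSE-by-week and feature-sweep tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    nortest,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
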