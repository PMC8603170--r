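Package: habitdtw
Title: Detecting Habitual App Use from Minute-Level Session Logs via
    Dynamic Time Warping
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies how temporally consistent a person's daily app use
    is, as an objective marker of habit. Each calendar day is converted to
    a 1440-minute binary use vector; a dynamic time warping (DTW) distance
    between consecutive days, with a penalty for nonuse and normalisation
    by mean daily use, yields a temporal-similarity statistic that is
    averaged within nonoverlapping 14-day intervals. The package provides
    session-log and survey ingest, interval/feature engineering with
    session-type, clock-time and weekday/weekend stratification,
    dichotomous future-use and self-reported health-benefit outcomes,
    logistic odds-ratio models, paired ROC AUC comparison (DeLong),
    random-forest variable importance, and a seeded synthetic cohort
    generator so the full pipeline can be exercised end to end without
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
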