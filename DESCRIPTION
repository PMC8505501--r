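Package: hadscreen
Title: Two-Cycle Screening of High-Alert Drug Prescription Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens visit-level hospital prescription records for probable
    high-alert-drug (HAD) prescription errors. Implements a two-cycle
    protocol: a gradient-boosted binary HAD-use screen whose probability cut
    point maximises a recall-weighted screening index (S-index = F1 x
    recall), a prevalence-based post-hoc readjustment of the confusion
    matrix driven by per-diagnosis HAD-use prevalence ("HAD percent"), a
    seven-class HAD-type screen with percentile uncertainty zones, and a
    HAD-ICD10 mismatch report that flags prescriptions unsupported by both
    the model and the prevalence evidence. Ships a seeded synthetic
    electronic-health-record generator with ground truth for every planted
    error so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    class,
    e1071,
    optparse,
    ranger,
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
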