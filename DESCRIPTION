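Package: trajresponse
Title: Detecting Imaging Response to Treatment from Longitudinal Trajectory Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting an imaging response to treatment from
    longitudinal, tabular imaging-derived features, as in routine multiple
    sclerosis MRI follow-up. Converts per-scan regional brain volumes and
    disconnection estimates into per-patient slope-sign trajectory features
    collapsed across hemispheres, removes covariate confounds with Bayesian
    ridge regression and verifies removal adversarially, compares low- and
    high-dimensional classifiers (support vector machines and extremely
    randomised trees) under subject-constrained bootstrap cross-validation
    with greedy forward feature selection and AUC-weighted ensembling,
    builds permutation null models, and simulates randomised controlled
    trials to estimate achieved power via Fisher's exact test. Includes a
    synthetic cohort generator emulating the statistical structure of such
    feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
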