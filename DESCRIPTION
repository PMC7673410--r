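Package: wholenight
Title: Stage-Independent Whole-Night Sleep EEG Features for PTSD Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes stage-independent, whole-night features from overnight
    multichannel sleep EEG -- log band power, the coefficient of variation of
    the log power spectrum, and the weighted phase lag index over twelve
    frequency bands -- and carries them through a complete screening pipeline
    for discriminating posttraumatic stress disorder (PTSD) from non-PTSD
    subjects: band-pass filtering, 5-s epoching with two per-channel artifact
    rejection rules, log transformation of synchrony features, two-night
    concordance filtering (Lin's concordance correlation coefficient),
    age-effect screening and regression-based removal, per-night AUC screening
    with DeLong confidence intervals, distance-correlation feature clustering,
    recursive feature elimination with cross-validated ridge-stabilised
    logistic regression, threshold selection at target sensitivities, and
    prevalence-adjusted positive predictive value evaluation. A synthetic
    cohort generator emulates the statistical structure of a two-night sleep
    study at both the raw-signal and the feature-table level, so the full
    pipeline is testable without access to restricted clinical recordings.
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
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
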