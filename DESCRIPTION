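Package: veicans
Title: EEG-Based Grading of CAR-T Neurotoxicity (VE-ICANS)
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the Visual EEG-based ICANS (VE-ICANS) grading
    system for immune effector cell-associated neurotoxicity syndrome
    after CAR-T cell therapy: the published integer scoring table for
    qualitative EEG features, a constrained pairwise learning-to-rank
    algorithm (logistic ranking loss with ElasticNet penalty and
    sign/ordinal/integer coefficient constraints) that derives such
    tables from patient-day data, grouped stratified nested
    cross-validation with bootstrap confidence intervals and per-level
    ROC/AUC, ICE/ICANS clinical score assembly with reviewer
    reconciliation, cohort contingency statistics, and a synthetic
    cohort simulator for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
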