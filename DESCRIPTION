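Package: afuq
Title: Weakly Supervised Atrial Fibrillation Detection with Uncertainty
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for training binary atrial-fibrillation ECG classifiers
    from weak (surrogate-generated) labels and for quantifying the quality
    of their predictions. Includes a synthetic multi-lead ECG cohort
    generator with tunable rhythm, noise and out-of-distribution structure;
    a dilated 1D convolutional network with batch normalisation and dropout,
    trained with Adam and early stopping; confident-learning label cleaning
    (per-class probability thresholds, confident joint, iterative pruning);
    epistemic (Monte Carlo dropout) and aleatoric (test-time augmentation by
    random signal masking) uncertainty estimation; and calibration and
    group-comparison statistics (expected calibration error, Brier score,
    negative log-likelihood, Cohen's kappa, Mann-Whitney U tests with
    Bonferroni-Holm correction). An end-to-end experiment driver reproduces
    the full weak-supervision pipeline on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
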