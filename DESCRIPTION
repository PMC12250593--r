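Package: fedecg
Title: Privacy-Preserving Federated GRU Classification of 12-Lead ECG Arrhythmias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and evaluates federated learning with per-client
    personalized models and differentially private gradient updates for
    four-class arrhythmia classification (sinus bradycardia, atrial
    fibrillation, supraventricular tachycardia, sinus rhythm) from
    ten-second 12-lead electrocardiograms. Provides a synthetic ECG
    generator with class-dependent rhythm structure and a consistent
    13-feature clinical table, a sequential denoising pipeline
    (zero-phase Butterworth low-pass, LOESS baseline-wander removal,
    one-dimensional non-local means), a gated recurrent unit sequence
    classifier with optional clinical-feature fusion, L2 gradient
    clipping with Gaussian noise injection, size-weighted federated
    averaging, local fine-tuning for personalization, and multiclass
    diagnostic metrics (per-class precision, sensitivity, specificity,
    F1, Cohen's kappa, Matthews correlation coefficient).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
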