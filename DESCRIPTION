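Package: ecgrecon
Title: Reconstruction of 12-Lead ECGs from Reduced Lead Sets and
    Regression-to-the-Mean Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the feasibility of reconstructing the full 12-lead
    electrocardiogram from one or two measured leads. Provides a dipole-model
    synthetic ECG cohort generator with ground-truth fiducials, a 1D U-Net
    encoder-decoder generator trained either with a Wasserstein GAN gradient
    penalty plus L1 objective or with mean squared error, mean and samplewise
    linear baselines, an open ECG delineator and amplitude/interval measurement
    module, and a statistical evaluation suite (per-lead RMSE, error
    percentiles, paired t- and F-tests, Bland-Altman agreement, inter-lead
    marker correlations) that detects regression-to-the-mean in reconstructed
    signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
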