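Package: vergelab
Title: Vergence EEG Analysis: Wavelet Time-Frequency Maps, Cluster-Based
    Permutation Inference, and Diagnostic Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for electroencephalography recorded during
    vergence eye-movement tasks, aimed at characterising non-strabismic
    binocular vision dysfunction (NSBVD). Provides a synthetic two-group
    cohort generator with injectable band/region/time-window power effects
    and EDF+ export, the standard preprocessing chain (average reference,
    zero-phase notch and band-pass filtering, spherical-spline bad-channel
    interpolation, event-locked epoching), a continuous complex Morlet
    wavelet transform with an explicit scale-to-frequency mapping,
    grand-average waveforms and spherical-spline scalp topographies,
    cluster-mass permutation tests on time-frequency grids with a
    Monte-Carlo maximum-statistic null, nested leave-one-out
    cross-validation with in-fold z-scoring and t-test feature selection
    for linear SVM, LDA and KNN classifiers, and the clinical baseline
    statistics (Shapiro-Wilk gating, Welch t, Mann-Whitney U, chi-square)
    together with optometric subtype rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    withr
Config/testthat/edition: 3
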