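Package: libspec
Title: Classification Pipeline for Laser-Induced Breakdown Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end chemometric pipeline for classifying laser-induced
    breakdown spectroscopy (LIBS) emission spectra by geographical origin.
    Provides wavelet denoising with signal-to-noise-driven parameter search,
    area normalization, two-stage variable selection (near-zero standard
    deviation filtering followed by iterative random-forest permutation
    importance elimination with out-of-bag stopping), deterministic
    spectrum-to-matrix recombination for two-dimensional convolutional
    networks, three convolutional classifiers with a staged stochastic
    gradient descent schedule, classical baselines (LDA, KNN, SVM), and
    model interpretation via gradient saliency maps back-mapped to
    wavelengths and t-SNE views of intermediate layers. A hierarchical
    synthetic-spectrum generator (plant, tablet, ablation position) makes
    every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    randomForest,
    MASS,
    class,
    e1071,
    Rtsne,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
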