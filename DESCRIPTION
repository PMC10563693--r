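Package: mircos
Title: FT-MIR Authentication of Plant Material via Two-Dimensional
    Correlation Spectroscopy and Chemometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible workflow for two-class authentication of
    powdered plant material from Fourier-transform mid-infrared (FT-MIR)
    spectra. Provides a synthetic two-class spectrum generator with
    band-level class contrasts, spectral preprocessing (SNV, MSC,
    Savitzky-Golay smoothing and derivatives), Kennard-Stone sample-set
    partitioning, PCA and PLS-DA with permutation diagnostics, RBF-SVM
    grid search, generalized two-dimensional correlation spectroscopy
    (synchronous, asynchronous and integrated Hilbert-Noda maps),
    surface-image rendering of correlation maps, and a small residual
    convolutional network classifier over the rendered images, scored
    with confusion-matrix metrics (accuracy, sensitivity, specificity,
    effectivity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    signal,
    e1071,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jpeg,
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
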