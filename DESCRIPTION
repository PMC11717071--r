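Package: specalib
Title: Hyperspectral Calibration with CARS-UVE Wavelength Selection and a
    Whale-Optimized BiLSTM-Attention Regressor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end chemometric calibration of scalar analyte content
    (e.g. protein in milk powder, g/100 g) from visible/near-infrared
    hyperspectral reflectance spectra. Provides dark/white reflectance
    correction, the standard spectral preprocessing operators (mean
    centering, standardization, min-max scaling, Savitzky-Golay smoothing
    and derivatives) with train/test-safe fitted chains, a PLS1 core with
    cross-validated RMSECV, competitive adaptive reweighted sampling (CARS)
    and uninformative variable elimination (UVE) wavelength selection and
    their cascade, a bidirectional LSTM regressor with additive attention
    pooling trained by backpropagation through time, whale optimization
    (WOA) for bounded hyperparameter search, calibration metrics
    (R2, RMSE, RPD) with model-comparison reports, and a synthetic
    spectra generator emulating brand-structured milk-powder data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
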