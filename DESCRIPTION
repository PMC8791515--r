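Package: spectrasense
Title: Classification and Committee Sensitivity Analysis of ATR-FTIR Fingerprint Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for classifying mid-infrared (ATR-FTIR) absorbance spectra
    of tissue samples as benign or malignant and for locating the
    diagnostically informative wavenumber regions. Provides per-spectrum
    z-score normalisation, rubber-band (convex hull) baseline correction and
    fingerprint-window cropping; two-component principal component analysis;
    feed-forward neural networks with SELU activations, alpha-dropout and
    AdaGrad stochastic gradient descent trained from scratch; linear
    discriminant analysis, linear support vector machine, logistic
    regression, CART decision trees, random forests and naive Bayes
    benchmark classifiers; stratified Monte-Carlo cross-validation with six
    diagnostic metrics; and a neural-network-committee input-perturbation
    sensitivity analysis that scores each wavenumber by the mean squared
    output response. A synthetic-spectra generator with class-conditional
    Gaussian bands supports fully reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
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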