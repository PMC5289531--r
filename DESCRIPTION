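Package: enetbeta
Title: Elastic-Net Regression-Coefficient Variable Selection for Spectral
    Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Variable selection for multivariate calibration of
    high-collinearity spectrum data (e.g. near-infrared absorbance against a
    reference concentration). Implements the Enet-BETA procedure: an elastic
    net fit by cyclic coordinate descent ranks channels by the magnitude of
    their regression coefficients, sequential prefix refits trace an RMSEP
    curve over subset sizes, and a confidence-ratio relaxation trades a small
    loss of accuracy for a sparser, more interpretable model. Also provides
    the standard comparators (NIPALS partial least squares, PLS-BETA
    coefficient selection, forward stepwise selection with BIC), the usual
    evaluation criteria (RMSEP, NMSE, R-squared, AIC/BIC, K-fold cross
    validation), a generator of spectrum-like synthetic data with planted
    sparse truth, and a benchmark driver comparing all methods on a
    train/test split.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
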