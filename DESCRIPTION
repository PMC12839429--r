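Package: hfsof
Title: Hierarchical Feature Selection and Optimization for Multi-Class
    Ultrasound Image Diagnosis
Version: 0.1.0
Authors@R:
    person("HFSOF", "Maintainers", email = "maintainers@hfsof.dev",
           role = c("aut", "cre"))
Description: Implements a hierarchical feature-selection and classification
    framework for multi-class medical image diagnosis: kernel principal
    component analysis for nonlinear dimensionality reduction, an ensemble of
    three filter criteria (information gain, chi-square, symmetrical
    uncertainty) fused by per-feature median rank, maximum-scatter-difference
    discriminant thresholding, and wrapper optimization of a binary feature
    mask by the Whale Migration Algorithm (with a particle swarm baseline)
    under a cross-validated support-vector-machine macro-F1 fitness. Includes
    a full multi-class evaluation suite (confusion matrix, per-class and
    macro/weighted precision, recall, F1, one-vs-rest AUC), an ultrasound-like
    phantom and planted-feature synthetic data generator, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png,
    jpeg,
    yaml
Config/testthat/edition: 3
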