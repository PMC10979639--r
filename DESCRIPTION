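Package: scatnet
Title: SCAT-Inception Convolutional Networks for Brain Lesion MRI
    Classification
Version: 0.1.0
Authors@R:
    person("scatnet", "developers", email = "scatnet@example.org",
           role = c("aut", "cre"))
Description: Implements an inception-style convolutional classifier augmented
    with a spatial convolutional attention (SCAT) operator for distinguishing
    glioblastoma (GBM) from solitary brain metastasis (MET) on 2-D
    contrast-enhanced T1-weighted MRI slices. Provides the full experimental
    pipeline: a seeded synthetic lesion-phantom generator with nested
    core/edema masks, region dataset construction (core, edema, overall) with
    augmentation, case-level stratified k-fold cross-validation, Adam
    training of the network, and diagnostic evaluation (accuracy,
    sensitivity, specificity, ROC/AUC) at both slice and case granularity.
    All tensor operations, including the convolution and attention forward
    and backward passes, are implemented natively with 'RcppArmadillo'
    kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
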