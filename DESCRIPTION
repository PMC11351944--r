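Package: celseg
Title: Contrast-Enhancing Lesion Segmentation for Multiple Sclerosis MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A patch-based 3D segmentation pipeline for gadolinium
    contrast-enhancing lesions (CELs) in multiple sclerosis MRI. Provides a
    synthetic multi-contrast brain phantom generator, white-matter-lesion
    (WML) guided patch sampling and augmentation, a 3D U-Net style
    encoder-decoder network with dice and focal losses (including an
    imbalance-weighted variant), WML-guided patch inference with
    overlap-sum-and-clip reconstruction, rule-based lesion filtering, and
    lesion-level detection metrics with volume-stratified reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
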