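Package: dks
Title: Deep Keypoint Stadiometry for Atrial Septal Defect Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An interpretable pipeline for suggesting transcatheter versus
    surgical closure of atrial septal defects from multiview transthoracic
    echocardiograms. A multiscale-supervised stacked hourglass network with
    anatomical-aware pairwise/triplet supervision localizes anatomical
    keypoints in three standard views; keypoint distances are converted to
    millimetre measurements using the image's measuring scale; and an explicit
    Boolean rule engine over those measurements produces the closure plan and
    an occluder size suggestion against a device catalogue. Includes a
    synthetic echocardiogram-like data generator with known geometry so every
    stage is trainable and testable without clinical data, plus evaluation
    metrics (percentage of correct keypoints, classification metrics, mean
    absolute error, quadratic weighted kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
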