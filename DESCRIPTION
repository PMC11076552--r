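Package: casedifficulty
Title: Per-Case Prediction Difficulty Scoring with Neural Network Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Assigns each case in a labeled tabular classification dataset a
    prediction-difficulty (instance hardness) score in [0,1] using three
    neural-network-based metrics: the minimal hidden-layer width an ensemble
    of networks needs to classify the left-out case (CDmc), a second
    network's predicted probability that a first network misclassifies the
    case under a five-set rotation (CDdm), and a predictive-uncertainty score
    combining the miscentering and spread of an ensemble's predicted
    probabilities normalized against the uniform distribution (CDpu).
    Includes simulated dataset generators with controlled class overlap
    (Gaussian blobs, interleaving crescent moons, concentric circles),
    fifteen classical instance-hardness baselines (kDN, decision-tree,
    Naive-Bayes, class-skew, distance-based and feature-overlap measures),
    and a correlation-based evaluation protocol with p-value masking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rpart,
    vegan,
    ggplot2,
    yaml,
    withr,
    parallel,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    png,
    optparse,
    jsonlite
Config/testthat/edition: 3
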