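Package: satadapt
Title: Bayesian Adaptive Estimation of Speed-Accuracy Tradeoff Functions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trial-based Bayesian estimation of the speed-accuracy tradeoff
    (SAT) function measured with the response-signal paradigm, and a Bayesian
    adaptive, block-wise stimulus-selection procedure that places each block's
    stimulus-onset asynchrony (SOA) where the expected information gain about
    the SAT parameters is maximal. Includes an ex-Gaussian virtual-observer
    simulator, maximum-likelihood and grid-based Bayesian fitting of the
    exponential-approach SAT model from trial-wise response time and
    correctness, four comparable estimation procedures (method of constant
    stimuli with averaged or trial-wise fits, Bayesian trial-wise fitting, and
    the Bayesian adaptive procedure), and accuracy/precision evaluation of
    estimator performance over replicated simulated experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
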