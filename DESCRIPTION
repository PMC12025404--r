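Package: whalemse
Title: Multiscale Sample Entropy and Gaussian Mixture Modelling for Blue
    Whale Call Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection and classification of Antarctic blue whale
    vocalizations (Z calls and D calls) in continuous passive acoustic
    recordings. Implements multiscale sample entropy (MSE) feature
    extraction on coarse-grained signal segments, Gaussian mixture model
    (GMM) based feature reduction via mean posterior probabilities, and
    GMM clustering/classification, together with PCA, dynamic mode
    decomposition and continuous-wavelet baselines, a synthetic call
    simulator with SNR-controlled noise, and accuracy/error-rate
    evaluation over repeated trials.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
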