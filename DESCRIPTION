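Package: dfwm
Title: Dynamic Neural Field Models of Visual Working Memory Recall
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates cued color-recall (delayed estimation) experiments with
    dynamic neural field models of visual working memory. Provides a generic
    field integrator (Amari-type fields with difference-of-Gaussians lateral
    interactions, sigmoidal output, and additive noise), two model
    architectures -- a five-field model with parallel encoding and an extended
    model with a spatial pathway, inhibition-of-return, and autonomous
    sequential consolidation -- the cued-recall task paradigm (delay and
    zero-delay control conditions), maximum-likelihood fitting of circular
    mixture models (von Mises + uniform, with a three-component swap variant)
    to recall errors, and experiment-level summaries (condition-wise mixture
    fits, RMSE against behavioral reference values, and AIC model comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
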