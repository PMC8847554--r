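Package: lingnet
Title: Personalised Network Dynamics of Daily Language Features
Version: 0.1.0
Authors@R:
    person("Packaged", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates per-person regularised graphical vector-autoregressive
    (GVAR) networks from daily word-category time series derived from short
    timestamped documents, and tests whether network connectivity changes
    during self-reported depressive episodes. Includes dictionary-based text
    scoring, episode-interval recoding, EBIC model selection over a lasso
    penalty grid, strength centralities, case-dropping stability (CS)
    coefficients, within-subject episode-effect models with permutation and
    bootstrap controls, a random-network generalisation experiment, and a
    synthetic cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
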