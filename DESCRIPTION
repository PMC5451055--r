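Package: handnet
Title: Hand-Centred Visual Representations via Continuous-Transformation
    Hebbian Learning in a Hierarchical Competitive Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the development of hand-centred visual neurons in a
    four-layer competitive hierarchical network (VisNet architecture) driven by
    a purely Hebbian continuous-transformation (CT) learning rule with synaptic
    scaling. Includes a procedural hand-plus-target stimulus generator, a Gabor
    hypercolumn V1 front-end, information-theoretic response analyses
    (stimulus-specific single-cell and decoded multiple-cell information),
    hand-centred receptive-field classification with fractional location
    counting, and eigenimage (PCA) diagnostics of stimulus ensembles that
    predict whether hand-centred representations emerge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
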