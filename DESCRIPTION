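Package: cvcausal
Title: Complexity and Causality of Beat-to-Beat Cardiovascular Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A unified framework for quantifying the complexity of
    beat-to-beat cardiovascular series (heart period, systolic arterial
    pressure, respiration) and the Granger-style causality among them.
    Three estimators share one optimized non-uniform multivariate
    embedding: a linear model-based predictability index with Akaike
    order selection, a model-free local-predictability index built on
    k-nearest-neighbor zero-order prediction, and a model-free
    k-nearest-neighbor conditional-entropy index. Also implements the
    baroreflex sequence method (BRS, BEI), window selection with a
    stationarity heuristic, a synthetic generator of coupled series with
    known causal structure, and normality-gated association of indexes
    with a cohort covariate such as age.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    nortest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
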