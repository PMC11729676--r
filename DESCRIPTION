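Package: quantgap
Title: Quantile Regression-Based Decomposition of Between-Group Outcome Gaps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes a between-group disparity in a continuous health
    outcome into a covariates (composition) part and a coefficients
    (structure) part at every quantile of the outcome distribution, using
    linear quantile regression and counterfactual marginal quantile
    functions in the Machado-Mata / Chernozhukov-Fernandez-Val-Melly
    tradition. Provides percentile-bootstrap pointwise confidence
    intervals, a mapping of the two parts onto population health
    strategies (proportionate universalism versus targeted approaches,
    with countervailing-covariate flags), a location-scale synthetic-data
    generator with known ground-truth decompositions, and table and
    report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
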