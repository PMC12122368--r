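Package: reefrestore
Title: Global Coral-Restoration Audit: Site Selection, Success, Thermal Risk and Cost
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit coral-reef restoration at the global scale: a
    synthetic generator for gridded reef-locality data with configurable
    covariate effects and spatial autocorrelation; spatial thinning with
    join-count and Moran's I independence screens; a boosted-regression-tree
    engine with holdout-deviance tree selection, relative influence and
    partial dependence; true-skill-statistic threshold optimisation for the
    restoration site-selection model; a standardized, survival-based
    restoration-success score and its cross-validated regression analysis;
    bleaching-alert exposure and projected degree-heating-week exceedance
    summaries; and per-hectare cost extrapolation for broad-scale
    restoration scenarios.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    xgboost,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
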