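Package: phonoflux
Title: Directed Cortical Network Dynamics of Phonotactic Repair
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for studying how word learning reshapes directed
    cortical influences during phoneme categorization. Identifies regions
    of interest from source-space activation maps by an
    activation-similarity algorithm, estimates time-varying multivariate
    autoregressive models with a Kalman filter, computes the per-timepoint
    Granger Causality Index with a residual-resampling bootstrap null,
    compares conditions by counts of significant timepoints with an exact
    binomial test and false-discovery-rate control, and provides the
    behavioral trial bookkeeping and psychometric analysis of phonotactic
    repair rates. A synthetic-data module generates every input with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
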