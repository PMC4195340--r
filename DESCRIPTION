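Package: nmabayes
Title: Bayesian Network Meta-Analysis for Dichotomous Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained engine for Bayesian network meta-analysis of
    arm-level binomial data. Implements the binomial-logit fixed- and
    random-effects consistency models and the unrelated-mean-effects
    inconsistency models with vague or informative heterogeneity priors,
    sampled by an adaptive random-walk Metropolis-within-Gibbs algorithm
    with multiple chains. Provides zero-cell continuity correction,
    evidence-network construction, Brooks-Gelman-Rubin and Monte-Carlo-error
    convergence checks, residual deviance and DIC model criticism,
    dev-dev inconsistency tables, SUCRA treatment ranking, league tables,
    forest and rankogram data, and a synthetic-data generator for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
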