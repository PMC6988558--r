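Package: marshBN
Title: Tree-Augmented Bayesian Network Habitat Analysis for Tidal-Marsh
    Small-Mammal Trap Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Habitat-association analysis of per-trap-night small-mammal
    survey data with discrete Bayesian networks. Provides case-file input and
    output with a covariate catalog, a synthetic trap-survey generator with a
    latent-Gaussian copula for correlated environmental covariates and planted
    habitat effects, Pearson correlation screening with greedy covariate
    elimination, equal-frequency discretization with minimum per-state support,
    naive and tree-augmented naive Bayes (TAN) structure induction via
    class-conditional mutual information, conditional-probability-table
    learning from cases, exact posterior inference with missing evidence
    marginalized over the covariate tree, confusion-table error partitioning
    with predicted-class denominators, spherical payoff scoring, stratified
    k-fold cross-validation, entropy-reduction sensitivity analysis, a
    multi-model suite runner with Pareto ranking, and Welch t / variance-ratio
    comparisons of habitat attributes between species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
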