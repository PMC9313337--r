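Package: pathwaybn
Title: Bayesian Network Reconstruction Strategies for Topology-Based Pathway Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Compares five strategies for converting cyclic biological pathway
    graphs into directed acyclic graphs suitable for Bayesian-network modelling:
    random edge insertion (PROPS-style), regression-significance-ranked
    insertion (Clipper-style), biological compartment/feedback rules with LASSO
    simplification (BNrich-style), cyclegroup rewiring (BPA-style), and a
    hierarchy-preserving ensemble of TrueSkill and social-agony decycling
    heuristics. Fits linear-Gaussian Bayesian networks on control samples by
    maximum likelihood, scores per-sample pathway log-likelihoods, classifies
    disease state with a Random Forest, and ranks pathways by mean decrease in
    Gini impurity. Ships a synthetic-data generator emulating paired
    tumor/normal expression cohorts with known ground truth, so the whole
    pipeline runs and is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests: glmnet, optparse, testthat (>= 3.0.0)
Config/testthat/edition: 3
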