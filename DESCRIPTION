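Package: famcoag
Title: Familial Co-Aggregation and Bivariate Liability-Threshold ACE
    Modelling for Register Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for register-based familial co-aggregation studies of two
    binary lifetime traits, modelled on Nordic national health registers.
    Provides a register-shaped data model with validation, a synthetic
    three-generation pedigree generator driven by a bivariate
    liability-threshold ACE model, index-relative pair cohort construction
    (parents, full siblings, aunts, uncles, cousins) with side labels and
    family clustering, configurable lifetime case definitions over
    era-dependent ICD and ATC codes, cluster-robust logistic odds-ratio
    estimation with natural cubic spline birth-year adjustment, regression
    standardization for marginal absolute risks, ratio-of-odds-ratio
    contrasts for maternal effects, and maximum-likelihood bivariate
    liability-threshold ACE variance decomposition on sibling and cousin
    pairs with AIC model selection.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    splines,
    sandwich,
    jsonlite,
    yaml,
    igraph
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mvtnorm
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
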