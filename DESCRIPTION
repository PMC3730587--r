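Package: sisterdiv
Title: Sexual Selection and Phenotypic Divergence in Sister-Species Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-method toolkit for testing whether sexual selection,
    indexed by plumage dichromatism, accelerates phenotypic divergence and
    diversification across recently split bird lineage pairs. Provides
    spectrophotometric plumage scoring via principal components,
    dichromatism indices, standardized trait-divergence metrics,
    maximum-likelihood Brownian-motion and Ornstein-Uhlenbeck sister-pair
    divergence models with rates linear in dichromatism (AICc model
    selection), a simulation-based birth-death likelihood for sister-species
    ages with an exponential lag-time to species recognition, linear mixed
    models and phylogenetic generalized least squares with maximum-likelihood
    Pagel's lambda, and synthetic-data generators with known truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    lme4,
    lmerTest,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
RoxygenNote: 7.3.3
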