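Package: pollshift
Title: Ordering Environmental and Pollinator Shifts on Dated Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers whether colonization of a novel environment preceded,
    followed, or co-occurred with pollinator shifts on a dated phylogeny.
    Combines continuous-time Markov (Mk) and state-dependent diversification
    (MuSSE-style) likelihoods with AIC model selection, marginal ancestral
    state reconstruction, a shift-path extractor and 1:1-line scenario
    classifier, correlated-evolution tests on product state spaces,
    phylogenetically corrected regressions (binary GLMM, GLS, simulation-based
    ANOVA, two-sample tests, stepwise reduction, occurrence resampling), and
    climate-niche summarization of occurrence records including Whittaker
    biome assignment. A synthetic-data module generates birth-death trees and
    paired trait histories with known shift ordering so every stage is
    testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    phytools,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
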