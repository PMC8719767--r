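Package: morphburden
Title: Hierarchical Analysis of Parasite Burden Across Host Color Morphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the full inference chain linking host sex, color morph
    and metazoan parasite burden in demersal fishes such as lingcod (Ophiodon
    elongatus): a negative-binomial generalized linear mixed model for
    per-taxon parasite counts with nested host random intercepts, correlated
    taxon-level random slopes for the sex-by-color interaction and a
    log-length offset, fitted by Laplace-approximated maximum likelihood;
    constrained color-relabelling permutation tests for the interaction;
    permutational multivariate analysis of variance (PERMANOVA) on
    Bray-Curtis dissimilarities of parasite communities; body-condition
    indices (Fulton's K, hepatosomatic index) with mixed-model post-hoc
    analyses; contingency analysis of morph frequency by sex; and a
    synthetic-data generator that draws host tables and count tables from the
    exact generative model the burden model assumes, so every stage is
    testable end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmmTMB,
    jsonlite,
    MASS,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
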