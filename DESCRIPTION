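Package: demopace
Title: Comparative Plant Demography from Stage-Structured Projection Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparative demographic analysis of stage-structured
    plant projection matrices: record validation and eligibility filtering,
    age-from-stage Markov-chain decomposition into survivorship and fertility
    schedules, life-history traits (longevity, Keyfitz entropy, age at first
    reproduction, mean life expectancy, reproductive entropy, net reproductive
    rate, population growth rate), eigenvalue elasticity analysis grouped into
    survival, growth and fertility processes, Bray-Curtis/UPGMA clustering with
    K-means guided cluster-count selection, PERMANOVA, PCA, and Bayesian
    estimation of Pagel's lambda phylogenetic signal by Markov chain Monte
    Carlo. Includes synthetic-data generators (life-history archetypes, random
    valid matrices, cohort simulation, Yule trees, Brownian-motion traits) and
    a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    phytools,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
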