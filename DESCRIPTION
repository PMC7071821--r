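Package: floranet
Title: Comparative Flower-Development Co-Expression Networks, Module
    Preservation, Phylogenetic Trait Association, and Evolutionary Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds stage-specific signed weighted gene co-expression
    networks across species from orthogroup expression matrices (biweight
    midcorrelation, soft thresholding against scale-free topology, signed
    topological overlap, dynamic dendrogram cutting and eigengene merging),
    identifies module hubs and network periphery, quantifies cross-stage
    module preservation with permutation Zsummary and medianRank statistics
    against a random "gold" module, tests module eigengene association with
    categorical floral traits (pollination syndrome, flower colour, shape,
    corolla spurs) under a phylogenetic probit mixed model sampled by MCMC
    over many trees with Gelman-Rubin and effective-sample-size diagnostics,
    and relates per-orthogroup evolutionary rates (Nei-Gojobori dN/dS) to
    network connectivity and expression via bootstrapped linear models and
    permutation t-tests. Ships a seeded synthetic-data generator (ultrametric
    phylogenies, trait tables, planted-module expression, codon alignments
    evolved at specified dN/dS) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    coda,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
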