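Package: sedcomm
Title: Community Ecology of Benthic Microbial Eukaryotes from OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream community-ecology analyses for benthic
    microbial-eukaryote metabarcoding surveys, starting from an OTU count
    table, a rooted OTU phylogeny, taxonomy assignments, and sample
    metadata. Implements rarefaction and alpha diversity (richness,
    Shannon, Faith's phylogenetic diversity), beta diversity (Bray-Curtis,
    unweighted UniFrac) with principal coordinates analysis, permutation
    statistics (ANOSIM, SIMPER, simple and partial Mantel tests, Spearman
    screens, distance-decay regression), null-model quantification of
    community assembly processes (weighted beta-mean-nearest-taxon
    distance, beta-nearest-taxon index, abundance-based Raup-Crick on
    Bray-Curtis) with a five-way process partition, and
    compositionality-robust SparCC co-occurrence networks with bootstrap
    significance, FDR control and graph-topology summaries. A synthetic
    community generator with known assembly regimes, phylogenetically
    conserved niche traits and environmental gradients supplies ground
    truth for validation, and a configurable pipeline orchestrates the
    full analysis reproducibly from a single seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    igraph,
    jsonlite,
    phangorn,
    phytools,
    picante,
    Rcpp,
    stats,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
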