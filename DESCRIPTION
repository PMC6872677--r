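Package: intertidr
Title: Diversity, Distance-Decay and Phylogenetic Null-Model Assembly
    Analysis for Intertidal Microeukaryote Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for site-by-OTU community surveys of
    intertidal microeukaryotes: rarefaction, alpha diversity (richness,
    Shannon, Faith's phylogenetic diversity), Bray-Curtis beta diversity,
    NMDS ordination, ANOSIM, Mantel and partial Mantel permutation tests,
    distance-decay of community similarity, environmental PCA, and a
    two-step phylogenetic null model (beta-nearest taxon index plus
    Bray-Curtis based Raup-Crick) that partitions community assembly into
    heterogeneous/homogeneous selection, dispersal limitation,
    homogenizing dispersal and ecological drift. Includes a synthetic
    community generator with controllable assembly regimes so every stage
    is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    picante,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
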