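Package: equitype
Title: Gut Microbiota Community Typing and Association Analysis for
    Endurance-Horse Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis pipeline for 16S rRNA gene surveys of the
    equine gut microbiota. Provides alpha-diversity profiling (Chao1, Shannon,
    Pielou evenness, dominance, rarity) with rarefaction, core-microbiota
    extraction, beta-diversity distances (weighted and unweighted UniFrac,
    Bray-Curtis, Euclidean) with PCoA and NMDS ordination, community typing by
    partitioning around medoids with silhouette-based selection of the number
    of clusters and cross-distance concordance checks, discriminant-genus
    ranking by PLS-DA with sparse PLS-DA cross-validation and sparse k-means,
    top-k genus-deletion robustness profiling, PCIT-filtered co-occurrence
    networks with topology scoring, association screening of community types
    against host, diet, fecal and metabolome variables (PERMANOVA, envfit,
    Mann-Whitney, Fisher, two-way ANOVA, probabilistic-quotient normalization
    of spectral bins), and simulation-based post-hoc power analysis. A
    Dirichlet-multinomial synthetic-cohort generator with a simulated
    phylogeny makes every stage testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    ape,
    vegan,
    mclust,
    igraph,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
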