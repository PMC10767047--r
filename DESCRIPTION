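Package: spatglia
Title: Spatiotemporal Analysis of Glial Activation in Spot-Based Spatial
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for spot-based (Visium-style) spatial
    transcriptomics of disease-model brains: log-normalization, variable-gene
    selection, PCA and SNN-Louvain region clustering with replicate QC,
    two-part hurdle-model differential expression with pseudobulk label-shuffle
    robustness checks, binned-control signature scoring of
    disease-associated microglia and astrocyte gene sets, rigid/affine
    registration of paired fluorescence images with patch-latent gene
    association, microglial-signature pseudotime over a principal tree with
    spatial mapping, and generic hypergeometric over-representation analysis.
    Includes a seeded synthetic-data generator that emulates a
    2 genotype x 2 age x 2 replicate study with white-matter-early /
    gray-matter-late glial activation, so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    igraph,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
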