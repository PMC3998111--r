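Package: tripnet
Title: Tripartite Gene-Chemical-Disease Interactome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and analysis of typed tripartite interaction
    networks linking genes, chemicals and diseases from curated
    association tables (CTD-style chemical-gene, chemical-disease and
    gene-disease records plus HPRD-style protein-protein interactions).
    Provides disease-context filtering and therapeutic-subset network
    construction with chemical co-occurrence inference, Jaccard
    neighbour-set similarity with linked-versus-unlinked Mann-Whitney
    comparison and sub-network percentile ranking, single-edge
    perturbation stability testing with Kolmogorov-Smirnov statistics, a
    reimplementation of the MCODE molecular-complex detection algorithm,
    binary-matrix hierarchical clustering with uncentered correlation and
    average linkage, similarity-threshold cluster extraction with
    inflection-point detection, candidate link inference, and a
    synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
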