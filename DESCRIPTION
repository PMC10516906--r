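Package: pmena
Title: Phylogenetic Null Models, RMT Co-Occurrence Networks, and
    Permutation Statistics for Microbiome Community Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream ecological-inference machinery for microbiome
    count data: between-community beta mean nearest taxon distance
    (betaMNTD) and the beta nearest taxon index (betaNTI) null-model
    classifier of community assembly processes, random matrix theory
    (RMT) based thresholding of taxon co-occurrence correlation
    networks, Bray-Curtis ordination (NMDS) with PERMANOVA, Mantel
    distance-matrix regressions, rank-sum screening with false
    discovery rate control, and the supporting normalization steps
    (rarefaction, RPKM, Z-scoring).  Includes synthetic-community
    generators with known assembly regimes and planted network modules
    so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    stats,
    tools,
    utils,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    picante,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
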