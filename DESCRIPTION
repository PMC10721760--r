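Package: plantpp
Title: Phylogenetic Profiling for Co-Evolving Gene Discovery in Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds normalized phylogenetic profile (NPP) matrices from
    all-vs-all best-hit bit-scores, detects genes that co-evolve with a
    query (gold-standard) gene set by clade-wise Ward hierarchical
    clustering scored with a maximal ratio score (MRS), validates the
    evolutionary signal with multilayer-perceptron and random-forest
    classifiers after Cluster-Centroids undersampling, and characterizes
    candidate genes by profile correlation and hypergeometric term
    enrichment. Includes a clade-structured synthetic-data generator with
    planted co-evolving modules so the whole pipeline is testable without
    external proteome data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
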