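Package: spaMoran
Title: Bivariate Moran Statistics for Spatial Ligand-Receptor Co-Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects spatially co-expressed ligand-receptor pairs in spatial
    transcriptomics with a bivariate extension of Moran's I ("Moran's R"),
    using either a permutation null or a closed-form (z-score) null derived
    from the exact permutation moments. Provides per-spot local statistics
    with sender/receiver decomposition and a quadrant filter, clustering of
    local interaction hits into tissue-level communication patterns, Fisher
    pathway enrichment, chord-diagram cell-type edge weights, and
    likelihood-ratio differential interaction testing across samples. Includes
    a seeded synthetic-data generator with controllable interaction variance
    fractions and an SVCA-style variance-component fit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
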