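Package: stinfer
Title: Genome-Wide Spatial Gene Expression Inference from Targeted Spatial
    Transcriptomics and Single-Cell RNA-Seq References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers genome-wide, single-cell-resolution spatial gene
    expression by integrating a targeted spatial-transcriptomic (ST)
    expression matrix with a scRNA-seq reference. Provides expression
    stabilization to suppress random false-positive/false-negative probe
    signals, a two-round integration (reciprocal-PCA anchoring followed by
    iterative-clustering harmonization) embedding both modalities in a
    shared space, weighted k-nearest-neighbor expression transfer from
    reference to spatial cells, permutation-based detection and clustering
    of spatially variable genes, gene-signature scoring, a hold-out /
    k-fold benchmarking protocol, and a synthetic paired-data generator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
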