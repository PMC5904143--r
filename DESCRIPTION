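Package: actionsc
Title: Archetypal Analysis of Single-Cell Transcriptomes with a
    Specificity-Weighted Similarity Kernel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the ACTION framework for characterizing the
    functional identity of single cells. A cell-to-cell similarity kernel
    suppresses universally expressed genes by projecting standardized
    expression profiles onto the orthogonal complement of the mean
    expression signature, and boosts cell-type-specific genes with
    entropy-based specificity weights. The cell space is decomposed into
    archetypes ("primary functions") via preconditioned successive
    projection and principal convex hull analysis, with the number of
    archetypes chosen automatically by an oversampling test on the
    archetype similarity graph. Archetype-specific transcriptional
    regulatory networks are inferred by minimum-hypergeometric (mHG)
    enrichment of transcription-factor regulons among residual-expression
    marker rankings, with exact dynamic-programming p-values. Includes a
    synthetic-data generator (labeled expression matrices with planted
    markers, regulons, separable instances and a dropout model), kernel
    k-means, and extrinsic clustering quality measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    mclust,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
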