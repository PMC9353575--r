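Package: scPolarity
Title: Reconstructing Germ-Disc Axial Polarity from Dissociated Single-Cell
    and Single-Nucleus Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for recovering the global anterior-posterior (radial)
    polarity and germ-layer organisation of an early spider germ disc from
    dissociated single-cell or single-nucleus RNA-seq count matrices. The
    package provides a negative-binomial synthetic germ-disc generator with
    per-cell ground truth (radial position, germ layer, rare subtypes,
    cell/nucleus modality), quality-control filters including a mode-relative
    molecule filter, log-normalisation, variable-feature selection and PCA,
    shared-nearest-neighbour graph clustering, Wilcoxon rank-sum differential
    expression with an iterative DEG-exclusion re-clustering loop that removes
    highly expressed ubiquitous genes responsible for spurious ectodermal
    splits, Ward (ward.D2) hierarchical clustering of cells over marker
    panels, quantitative polarity-axis reconstruction from 2D embeddings,
    expression-image rasterisation with normalized cross-correlation template
    matching and RGB composites, and a rare-cell marker filter for detecting
    small cell populations such as cumulus mesenchymal cells.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    uwot,
    png,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
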