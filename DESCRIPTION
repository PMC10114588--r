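Package: scLabelBoot
Title: Weighted Bootstrap Cell Type Label Transfer for Imbalanced References
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transfers cell type labels from an annotated single-cell RNA-seq
    reference to a query dataset while accounting for imbalanced cell type
    abundances in the reference. Implements a weighted bootstrap-annotation
    scheme that classifies the query against one abundance-matched reference
    subset per cell type, weights each subset's vote by how close the
    predicted label's abundance is to the subset's per-type cap, and
    aggregates by weighted majority. Ships lightweight implementations of
    correlation-, embedding- and forest-based label transfer algorithms, a
    shared Pearson-residual preprocessing workflow, reference-design utilities
    (per-type capped subsampling, permutation sweeps, multi-source mosaic
    assembly), per-cell-type evaluation and confidence-calibration reports,
    and a negative-binomial simulator of imbalanced PBMC-like datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    ranger,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, Annotation, Classification, RNASeq, Software
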