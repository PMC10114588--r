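#' @import methods
#' @importFrom stats quantile median cor rnbinom rlnorm runif sd setNames
#'   wilcox.test p.adjust aggregate
#' @importFrom utils head write.csv read.csv
#' @importFrom Rcpp evalCpp
#' @useDynLib scLabelBoot, .registration = TRUE
NULL

#' Sentinel label for cells a classifier declines to annotate
#'
#' Classifiers emit this label for query cells they cannot or will not assign
#' to any reference cell type (e.g. zero-signal cells, or cells a
#' random-profile-aware forest classifies as not belonging to any reference
#' type). Downstream, unassigned predictions always count as false
#' predictions for the cell's true type and carry zero weight in the
#' bootstrap aggregation.
#'
#' @return A length-one character string.
#' @examples
#' unassignedLabel()
#' @export
unassignedLabel <- function() "unassigned"

#' ProcessedExpression: HVG-restricted, log-transformed, L2-normalized matrix
#'
#' Holds the shared feature representation all classifiers consume: the
#' expression of the selected highly variable genes after
#' \code{log(count + pseudocount)} transformation and cell-wise L2
#' normalization. Genes are rows, cells are columns. Cells whose transformed
#' profile has (numerically) zero norm are kept as zero columns and flagged
#' in \code{zeroCells}; classifiers must emit \code{unassignedLabel()} for
#' them instead of failing.
#'
#' @slot values numeric matrix, selected genes x cells; every non-flagged
#'   column has unit L2 norm.
#' @slot hvgIds character, the selected gene ids (rownames of \code{values}).
#' @slot params list with at least \code{nHvgs}, \code{pseudocount},
#'   \code{theta}.
#' @slot zeroCells logical, one entry per cell; \code{TRUE} for zero-norm
#'   cells.
#' @exportClass ProcessedExpression
setClass("ProcessedExpression",
    representation(
        values = "matrix",
        hvgIds = "character",
        params = "list",
        zeroCells = "logical"
    )
)

setValidity("ProcessedExpression", function(object) {
    v <- object@values
    if (nrow(v) != length(object@hvgIds))
        return("nrow(values) must equal length(hvgIds)")
    if (ncol(v) != length(object@zeroCells))
        return("zeroCells must have one entry per cell")
    if (is.null(colnames(v)))
        return("values must carry cell ids as colnames")
    nrm <- sqrt(colSums(v^2))
    bad <- !object@zeroCells & abs(nrm - 1) > 1e-8
    if (any(bad))
        return(sprintf("%d non-flagged cells deviate from unit L2 norm",
                       sum(bad)))
    if (any(nrm[object@zeroCells] > 1e-8))
        return("flagged zero cells must be all-zero columns")
    TRUE
})

#' ClassifierSpec: a label transfer algorithm plus its parameters
#'
#' @slot name one of \code{"centroid"}, \code{"singler_like"},
#'   \code{"cca_mnn"}, \code{"toppair_forest"}.
#' @slot params method-specific parameter list (validated at fit time).
#' @slot seed integer seed used by stochastic classifiers.
#' @exportClass ClassifierSpec
setClass("ClassifierSpec",
    representation(name = "character", params = "list", seed = "integer")
)

setValidity("ClassifierSpec", function(object) {
    ok <- c("centroid", "singler_like", "cca_mnn", "toppair_forest")
    if (length(object@name) != 1L || !object@name %in% ok)
        return(sprintf("name must be one of %s", paste(ok, collapse = ", ")))
    TRUE
})

#' ReferenceSubset: a per-type capped subsample of a reference dataset
#'
#' @slot cellIndices integer indices (columns) into the parent dataset.
#' @slot cap integer, maximum cells per cell type in the subset.
#' @slot seed integer sampling seed.
#' @slot parentId character id of the parent dataset.
#' @exportClass ReferenceSubset
setClass("ReferenceSubset",
    representation(cellIndices = "integer", cap = "integer",
                   seed = "integer", parentId = "character")
)

setValidity("ReferenceSubset", function(object) {
    if (anyDuplicated(object@cellIndices))
        return("cellIndices must be unique (sampling without replacement)")
    if (length(object@cap) != 1L || object@cap < 1L)
        return("cap must be a single integer >= 1")
    TRUE
})

#' SubsetSeries: one abundance-matched subset per reference cell type
#'
#' The subset series is the sampling design of the weighted bootstrap: for a
#' reference with K cell types of abundances n_1..n_K, the series holds K
#' subsets, the j-th drawn with per-type cap n_j. The subset whose cap is the
#' largest abundance is the full reference.
#'
#' @slot subsets list of \linkS4class{ReferenceSubset}, one per cell type.
#' @slot caps integer vector of per-subset caps (the type abundances).
#' @slot typeNames character, the cell type that set each subset's cap.
#' @exportClass SubsetSeries
setClass("SubsetSeries",
    representation(subsets = "list", caps = "integer", typeNames = "character")
)

setValidity("SubsetSeries", function(object) {
    if (length(object@subsets) != length(object@caps) ||
        length(object@caps) != length(object@typeNames))
        return("subsets, caps and typeNames must be parallel")
    if (!all(vapply(object@subsets, is, logical(1), "ReferenceSubset")))
        return("subsets must all be ReferenceSubset objects")
    TRUE
})

#' BootstrapResult: votes, weights and aggregated labels of a bootstrap run
#'
#' @slot votes data.frame with columns cell_id, replicate, subset_cap,
#'   subset_type, label, weight: one row per (query cell, subset, replicate).
#' @slot scoreTable numeric matrix, query cells x reference labels, holding
#'   the summed vote weights.
#' @slot predictions data.frame with cell_id, label, confidence (the
#'   weight-weighted agreement of the votes with the winner).
#' @slot nBoot integer number of independent subset-series replicates.
#' @exportClass BootstrapResult
setClass("BootstrapResult",
    representation(votes = "data.frame", scoreTable = "matrix",
                   predictions = "data.frame", nBoot = "integer")
)

#' EvaluationReport: confusion matrix and per-cell-type metrics
#'
#' Per-type "accuracy" is recall/sensitivity: the fraction of a type's query
#' cells recovered. Precision is the fraction of cells predicted as that type
#' that truly belong to it. Unassigned predictions count against their true
#' type's recall and appear in a dedicated confusion column.
#'
#' @slot confusion integer matrix, true types x (predicted types +
#'   unassigned).
#' @slot perClass data.frame with cell_type, support, accuracy, precision, f1.
#' @slot macroF1 unweighted mean of per-class F1.
#' @slot microF1 micro-averaged F1 (= overall accuracy over all cells).
#' @exportClass EvaluationReport
setClass("EvaluationReport",
    representation(confusion = "matrix", perClass = "data.frame",
                   macroF1 = "numeric", microF1 = "numeric")
)

setValidity("EvaluationReport", function(object) {
    pc <- object@perClass
    need <- c("cell_type", "support", "accuracy", "precision", "f1")
    if (!all(need %in% names(pc)))
        return("perClass must have cell_type, support, accuracy, precision, f1")
    m <- as.matrix(pc[, c("accuracy", "precision", "f1")])
    if (any(m < -1e-12 | m > 1 + 1e-12, na.rm = TRUE))
        return("metrics must lie in [0, 1]")
    TRUE
})

#' SyntheticSpec: generative description of a planted-structure scRNA-seq set
#'
#' @slot cellTypes data.frame with columns name, abundance.
#' @slot nGenes integer number of genes.
#' @slot markersPerType integer markers per cell type.
#' @slot markerFold numeric > 1, multiplicative up-regulation of markers.
#' @slot relatedPairs data.frame with typeA, typeB, sharedFraction.
#' @slot baselineMeanLogdist numeric length-2 (meanlog, sdlog) of the
#'   per-gene lognormal baseline mean.
#' @slot dispersion numeric NB overdispersion theta (variance =
#'   mu + mu^2/theta).
#' @slot libsizeLogdist numeric length-2 (meanlog, sdlog) of the per-cell
#'   library size factor.
#' @slot batches data.frame with name, fraction, batchEffectSigma.
#' @slot seed integer master seed; fixes gene-level structure (baselines,
#'   marker map, batch factors).
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    representation(
        cellTypes = "data.frame", nGenes = "integer",
        markersPerType = "integer", markerFold = "numeric",
        relatedPairs = "data.frame", baselineMeanLogdist = "numeric",
        dispersion = "numeric", libsizeLogdist = "numeric",
        batches = "data.frame", seed = "integer"
    )
)

setValidity("SyntheticSpec", function(object) {
    ct <- object@cellTypes
    if (!all(c("name", "abundance") %in% names(ct)))
        return("cellTypes needs columns name, abundance")
    if (any(ct$abundance < 1)) return("abundances must be >= 1")
    if (anyDuplicated(ct$name)) return("cell type names must be unique")
    if (object@markersPerType * nrow(ct) > object@nGenes)
        return("markersPerType * K must not exceed nGenes")
    if (object@markerFold < 1)
        return("markerFold must be at least 1 (1 = no marker signal)")
    if (abs(sum(object@batches$fraction) - 1) > 1e-8)
        return("batch fractions must sum to 1")
    rp <- object@relatedPairs
    if (nrow(rp) > 0) {
        if (!all(c(rp$typeA, rp$typeB) %in% ct$name))
            return("relatedPairs reference unknown cell types")
        if (any(rp$sharedFraction < 0 | rp$sharedFraction > 1))
            return("sharedFraction must lie in [0, 1]")
    }
    TRUE
})

setMethod("show", "ProcessedExpression", function(object) {
    cat(sprintf("ProcessedExpression: %d HVGs x %d cells (%d zero-norm)\n",
        nrow(object@values), ncol(object@values), sum(object@zeroCells)))
    cat(sprintf("  params: nHvgs=%s pseudocount=%g theta=%g\n",
        object@params$nHvgs, object@params$pseudocount, object@params$theta))
})

setMethod("show", "ClassifierSpec", function(object) {
    cat(sprintf("ClassifierSpec '%s' (seed %d)\n", object@name, object@seed))
    if (length(object@params))
        cat("  params:", paste(names(object@params), unlist(object@params),
            sep = "=", collapse = " "), "\n")
})

setMethod("show", "SubsetSeries", function(object) {
    cat(sprintf("SubsetSeries: %d subsets, caps %s\n",
        length(object@subsets), paste(object@caps, collapse = ", ")))
})

setMethod("show", "BootstrapResult", function(object) {
    cat(sprintf("BootstrapResult: %d cells, %d labels, %d votes/cell (nBoot=%d)\n",
        nrow(object@scoreTable), ncol(object@scoreTable),
        nrow(object@votes) / max(1L, nrow(object@scoreTable)), object@nBoot))
})

setMethod("show", "EvaluationReport", function(object) {
    cat(sprintf("EvaluationReport: %d cells, %d cell types\n",
        sum(object@confusion), nrow(object@perClass)))
    cat(sprintf("  macro F1 %.3f, micro F1 %.3f\n",
        object@macroF1, object@microF1))
    print(object@perClass, row.names = FALSE, digits = 3)
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf("SyntheticSpec: %d cell types, %d cells, %d genes (seed %d)\n",
        nrow(object@cellTypes), sum(object@cellTypes$abundance),
        object@nGenes, object@seed))
    cat("  abundances:", paste(object@cellTypes$name,
        object@cellTypes$abundance, sep = ":", collapse = " "), "\n")
})
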