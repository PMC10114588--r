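#' Construct a validated expression dataset
#'
#' The package's dataset container is a
#' \link[SingleCellExperiment]{SingleCellExperiment} with a sparse
#' \code{counts} assay (genes in rows, cells in columns), unique gene and
#' cell ids as dimnames, and optional per-cell \code{label} and \code{batch}
#' columns in \code{colData}. This constructor validates the invariants every
#' downstream operation relies on: non-negative finite counts, no duplicate
#' ids, labels/batches aligned with cells and free of empty strings.
#'
#' @param counts matrix or sparse Matrix of non-negative counts, genes x
#'   cells.
#' @param geneIds,cellIds character vectors of unique ids; defaults to the
#'   dimnames of \code{counts}.
#' @param labels optional per-cell cell type labels (character).
#' @param batch optional per-cell batch/source tags (character).
#' @return A \code{SingleCellExperiment}.
#' @examples
#' counts <- matrix(rpois(12, 2), nrow = 3,
#'     dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' ds <- ExpressionDataset(counts, labels = c("A", "A", "B", "B"))
#' cellLabels(ds)
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Matrix Matrix readMM writeMM colSums rowSums t
#' @export
ExpressionDataset <- function(counts, geneIds = rownames(counts),
                              cellIds = colnames(counts),
                              labels = NULL, batch = NULL) {
    if (is.null(geneIds) || is.null(cellIds))
        stop("gene and cell ids are required")
    geneIds <- as.character(geneIds)
    cellIds <- as.character(cellIds)
    if (length(geneIds) != nrow(counts) || length(cellIds) != ncol(counts))
        stop(sprintf(
            "count matrix is %d genes x %d cells but %d gene ids and %d cell ids were given",
            nrow(counts), ncol(counts), length(geneIds), length(cellIds)))
    if (anyDuplicated(geneIds)) stop("duplicate gene ids")
    if (anyDuplicated(cellIds)) stop("duplicate cell ids")
    if (!methods::is(counts, "sparseMatrix"))
        counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
    vals <- counts@x
    if (length(vals) && (any(!is.finite(vals)) || any(vals < 0)))
        stop("counts must be finite and non-negative")
    dimnames(counts) <- list(geneIds, cellIds)
    cd <- S4Vectors::DataFrame(row.names = cellIds)
    if (!is.null(labels)) {
        labels <- as.character(labels)
        if (length(labels) != length(cellIds))
            stop("labels must have one entry per cell")
        if (any(is.na(labels)) || any(!nzchar(labels)))
            stop("labels must be non-empty strings")
        cd$label <- labels
    }
    if (!is.null(batch)) {
        batch <- as.character(batch)
        if (length(batch) != length(cellIds))
            stop("batch must have one entry per cell")
        cd$batch <- batch
    }
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts), colData = cd)
}

#' Accessors for expression datasets
#'
#' Small accessors over the \code{SingleCellExperiment} dataset container:
#' gene ids, cell ids, per-cell labels and batch tags, and the per-type
#' abundance table.
#'
#' @param x a dataset built with \code{\link{ExpressionDataset}}.
#' @return \code{geneIds}/\code{cellIds}: character vectors.
#'   \code{cellLabels}/\code{cellBatches}: character vectors or \code{NULL}
#'   when absent. \code{typeAbundances}: named integer vector of cells per
#'   cell type, decreasing.
#' @name dataset-accessors
NULL

#' @rdname dataset-accessors
#' @export
geneIds <- function(x) rownames(x)

#' @rdname dataset-accessors
#' @export
cellIds <- function(x) colnames(x)

#' @rdname dataset-accessors
#' @export
cellLabels <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("label" %in% names(cd)) as.character(cd$label) else NULL
}

#' @rdname dataset-accessors
#' @export
cellBatches <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("batch" %in% names(cd)) as.character(cd$batch) else NULL
}

#' @rdname dataset-accessors
#' @export
typeAbundances <- function(x) {
    lab <- cellLabels(x)
    if (is.null(lab)) stop("dataset carries no labels")
    tab <- table(lab)
    out <- as.integer(tab)
    names(out) <- names(tab)
    sort(out, decreasing = TRUE)
}

.requireLabels <- function(x) {
    lab <- cellLabels(x)
    if (is.null(lab)) stop("dataset carries no labels", call. = FALSE)
    lab
}
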