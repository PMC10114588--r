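#' Read a count dataset from Matrix Market plus id files
#'
#' Reads the common on-disk triple of scRNA-seq pipelines: a Matrix Market
#' coordinate file of counts, one-gene-per-line and one-cell-per-line id
#' files, and an optional CSV label table (\code{cell_id,label[,batch]}).
#' Most distributions (10x among them) store the matrix genes x cells, which
#' is the default orientation; set \code{orientation = "cells_by_genes"} for
#' transposed files. Label rows are matched to cells by id, never by order.
#'
#' @param matrixPath path to the .mtx file.
#' @param genesPath,cellsPath paths to the plain-text id files.
#' @param labelsPath optional path to the label CSV.
#' @param orientation orientation of the stored matrix.
#' @return A dataset as built by \code{\link{ExpressionDataset}}.
#' @export
readMtxDataset <- function(matrixPath, genesPath, cellsPath,
                           labelsPath = NULL,
                           orientation = c("genes_by_cells",
                                           "cells_by_genes")) {
    orientation <- match.arg(orientation)
    m <- Matrix::readMM(matrixPath)
    if (orientation == "cells_by_genes") m <- Matrix::t(m)
    genes <- readLines(genesPath)
    cells <- readLines(cellsPath)
    genes <- genes[nzchar(genes)]
    cells <- cells[nzchar(cells)]
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
        stop(sprintf(
            "matrix is %d x %d after orientation but there are %d genes and %d cells",
            nrow(m), ncol(m), length(genes), length(cells)))
    labels <- NULL
    batch <- NULL
    if (!is.null(labelsPath)) {
        lt <- utils::read.csv(labelsPath, stringsAsFactors = FALSE,
                              colClasses = "character")
        if (!all(c("cell_id", "label") %in% names(lt)))
            stop("label table needs columns cell_id and label")
        if (anyDuplicated(lt$cell_id))
            stop("duplicate cell_id in label table")
        missing <- setdiff(lt$cell_id, cells)
        if (length(missing))
            stop(sprintf("label table references unknown cells: %s",
                         paste(utils::head(missing, 5), collapse = ", ")))
        idx <- match(cells, lt$cell_id)
        if (any(is.na(idx)))
            stop(sprintf("%d cells have no label row", sum(is.na(idx))))
        labels <- lt$label[idx]
        if ("batch" %in% names(lt)) batch <- lt$batch[idx]
    }
    ExpressionDataset(m, geneIds = genes, cellIds = cells,
                      labels = labels, batch = batch)
}

#' Write and read prediction tables
#'
#' Predictions travel as a data.frame with columns \code{cell_id},
#' \code{label} and \code{confidence} (\code{NA} when a classifier supplies
#' none). The CSV uses the header \code{cell_id,predicted_label,confidence}
#' with missing confidences written as empty fields; writing then reading
#' reproduces the table exactly.
#'
#' @param predictions data.frame with cell_id, label, optional confidence.
#' @param path file path.
#' @return \code{writePredictionsCsv}: the path, invisibly.
#'   \code{readPredictionsCsv}: the prediction data.frame.
#' @export
writePredictionsCsv <- function(predictions, path) {
    stopifnot(all(c("cell_id", "label") %in% names(predictions)))
    out <- data.frame(
        cell_id = as.character(predictions$cell_id),
        predicted_label = as.character(predictions$label),
        confidence = if ("confidence" %in% names(predictions))
            as.numeric(predictions$confidence) else rep(NA_real_,
                                                        nrow(predictions)),
        stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, na = "")
    invisible(path)
}

#' @rdname writePredictionsCsv
#' @export
readPredictionsCsv <- function(path) {
    x <- utils::read.csv(path, stringsAsFactors = FALSE,
        colClasses = c(cell_id = "character",
                       predicted_label = "character",
                       confidence = "numeric"))
    data.frame(cell_id = x$cell_id, label = x$predicted_label,
               confidence = x$confidence, stringsAsFactors = FALSE)
}

#' Concatenate datasets sharing a gene panel
#'
#' Column-binds datasets measured on an identical, identically ordered gene
#' panel into one dataset, tagging every cell with its source batch and
#' disambiguating cell ids as \code{"{batch}:{cell_id}"}. Counts pass through
#' numerically unchanged: no batch correction or rescaling of any kind is
#' applied.
#'
#' @param datasets list of datasets with identical \code{geneIds}.
#' @param batchNames character, one name per dataset.
#' @return A combined dataset with the \code{batch} column filled.
#' @export
concatenateDatasets <- function(datasets, batchNames) {
    stopifnot(length(datasets) >= 1L,
              length(batchNames) == length(datasets))
    genes <- geneIds(datasets[[1L]])
    for (d in datasets)
        if (!identical(geneIds(d), genes))
            stop("datasets must share an identical, identically ordered gene list")
    countsList <- lapply(datasets, SummarizedExperiment::assay, "counts")
    newIds <- unlist(lapply(seq_along(datasets), function(i)
        paste0(batchNames[i], ":", cellIds(datasets[[i]]))))
    if (anyDuplicated(newIds))
        stop("duplicate cell ids after batch prefixing")
    counts <- do.call(cbind, countsList)
    labelsList <- lapply(datasets, cellLabels)
    labels <- if (all(!vapply(labelsList, is.null, logical(1))))
        unlist(labelsList) else NULL
    batch <- rep(batchNames,
                 vapply(datasets, ncol, integer(1)))
    ExpressionDataset(counts, geneIds = genes, cellIds = newIds,
                      labels = labels, batch = batch)
}

#' Write a dataset as Matrix Market plus id and label files
#'
#' Inverse of \code{\link{readMtxDataset}}: writes \code{matrix.mtx}
#' (genes x cells), \code{genes.txt}, \code{cells.txt} and, when labels are
#' present, \code{labels.csv} into a directory.
#'
#' @param dataset a dataset.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeMtxDataset <- function(dataset, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(SummarizedExperiment::assay(dataset, "counts"),
                    file.path(dir, "matrix.mtx"))
    writeLines(geneIds(dataset), file.path(dir, "genes.txt"))
    writeLines(cellIds(dataset), file.path(dir, "cells.txt"))
    lab <- cellLabels(dataset)
    if (!is.null(lab)) {
        df <- data.frame(cell_id = cellIds(dataset), label = lab,
                         stringsAsFactors = FALSE)
        b <- cellBatches(dataset)
        if (!is.null(b)) df$batch <- b
        utils::write.csv(df, file.path(dir, "labels.csv"), row.names = FALSE)
    }
    invisible(dir)
}

#' Read a dense delimited count table
#'
#' Reads a small dense count table (CSV/TSV with gene and cell ids) into a
#' dataset; the kind of table used for toy fixtures and spot checks rather
#' than full-size experiments, which travel as Matrix Market triples.
#'
#' @param path delimited file with row names in the first column.
#' @param sep field separator (default comma).
#' @param orientation whether rows are genes (default) or cells.
#' @param labelsPath optional label CSV as in \code{\link{readMtxDataset}}.
#' @return A dataset as built by \code{\link{ExpressionDataset}}.
#' @export
readDenseDataset <- function(path, sep = ",",
                             orientation = c("genes_by_cells",
                                             "cells_by_genes"),
                             labelsPath = NULL) {
    orientation <- match.arg(orientation)
    tab <- utils::read.table(path, sep = sep, header = TRUE,
                             row.names = 1, check.names = FALSE)
    m <- as.matrix(tab)
    if (orientation == "cells_by_genes") m <- t(m)
    labels <- NULL
    if (!is.null(labelsPath)) {
        lt <- utils::read.csv(labelsPath, colClasses = "character")
        idx <- match(colnames(m), lt$cell_id)
        if (any(is.na(idx))) stop("label table is missing cells")
        labels <- lt$label[idx]
    }
    ExpressionDataset(m, labels = labels)
}
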