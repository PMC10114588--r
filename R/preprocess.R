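#' Select highly variable genes by analytic Pearson residuals
#'
#' Ranks genes by the variance of their analytic Pearson residuals under the
#' null model of constant relative expression across cells: for count
#' \eqn{x_{cg}} the expected value is
#' \eqn{\mu_{cg} = rowsum_c \cdot colsum_g / grandsum} and the residual
#' \eqn{r_{cg} = (x_{cg} - \mu_{cg}) / \sqrt{\mu_{cg} + \mu_{cg}^2/\theta}},
#' clipped to \eqn{\pm\sqrt{n_{cells}}} so single outlier cells cannot
#' dominate the ranking. Genes are returned in descending order of residual
#' variance, ties broken by gene id, which makes the selection invariant to
#' cell and gene order.
#'
#' @param dataset a dataset with non-negative counts.
#' @param nHvgs number of genes to return (all genes, still ranked, if the
#'   dataset has fewer).
#' @param theta overdispersion of the null model (default 100).
#' @param clip residual clipping bound; defaults to \code{sqrt(n_cells)} as
#'   in the analytic Pearson-residual method. \code{Inf} disables clipping.
#' @return Character vector of the selected gene ids, best first.
#' @export
selectHvgsPearsonResiduals <- function(dataset, nHvgs = 1000, theta = 100,
                                       clip = NULL) {
    nHvgs <- .assertScalarCount(nHvgs, "nHvgs")
    counts <- SummarizedExperiment::assay(dataset, "counts")
    nCells <- ncol(counts)
    nGenes <- nrow(counts)
    cellSums <- Matrix::colSums(counts)
    geneSums <- Matrix::rowSums(counts)
    total <- sum(cellSums)
    if (total == 0) stop("all counts are zero; cannot rank genes")
    if (is.null(clip)) clip <- sqrt(nCells)
    # residuals over all cells (zeros included) in dense gene blocks: keeps
    # everything vectorized without materializing the full dense matrix
    tc <- Matrix::t(counts)          # cells x genes, columns are genes
    resVar <- numeric(nGenes)
    blockSize <- max(1L, floor(2e6 / max(1L, nCells)))
    p <- cellSums / total
    for (start in seq(1L, nGenes, by = blockSize)) {
        idx <- start:min(nGenes, start + blockSize - 1L)
        x <- as.matrix(tc[, idx, drop = FALSE])  # cells x block
        mu <- p %o% geneSums[idx]
        r <- (x - mu) / sqrt(mu + mu^2 / theta)
        r[!is.finite(r)] <- 0        # genes/cells with zero totals
        r <- pmin(pmax(r, -clip), clip)
        m <- colMeans(r)
        resVar[idx] <- (colSums(r^2) - nCells * m^2) / max(1L, nCells - 1L)
    }
    ids <- geneIds(dataset)
    ord <- order(-resVar, ids)
    ids[ord][seq_len(min(nHvgs, nGenes))]
}

#' Log-transform and L2-normalize a dataset on a gene panel
#'
#' Restricts the counts to \code{hvgIds}, applies
#' \code{log(count + pseudocount)} and scales every cell to unit L2 norm.
#' Note the convention: with the default pseudocount of 0.001 a zero count
#' maps to \eqn{\log(0.001) \approx -6.9}, not to 0 — unlike the common
#' \code{log1p} transform, cells with no counts on the panel still carry a
#' well-defined (constant negative) profile and are normalized like any
#' other. Only cells whose transformed profile is numerically all-zero are
#' left as zero vectors and flagged in \code{zeroCells}; classifiers treat
#' those as unassignable.
#'
#' @param dataset a dataset.
#' @param hvgIds gene ids to keep (subset of the dataset's genes), e.g. from
#'   \code{\link{selectHvgsPearsonResiduals}}.
#' @param pseudocount value added before the log (default 0.001).
#' @param theta recorded in the params slot for provenance (the HVG-model
#'   theta); not used by the transform itself.
#' @return A \linkS4class{ProcessedExpression}.
#' @examples
#' ds <- ExpressionDataset(matrix(c(0, 0, 3, 3), nrow = 2,
#'     dimnames = list(c("g1", "g2"), c("c1", "c2"))))
#' p <- logL2Normalize(ds, c("g1", "g2"))
#' processedValues(p)[, "c1"]  # (-1, -1) / sqrt(2)
#' @export
logL2Normalize <- function(dataset, hvgIds, pseudocount = 0.001,
                           theta = 100) {
    if (pseudocount <= 0) stop("pseudocount must be positive")
    unknown <- setdiff(hvgIds, geneIds(dataset))
    if (length(unknown))
        stop(sprintf("unknown gene ids: %s",
                     paste(utils::head(unknown, 5), collapse = ", ")))
    counts <- SummarizedExperiment::assay(dataset, "counts")[hvgIds, ,
                                                             drop = FALSE]
    v <- log(as.matrix(counts) + pseudocount)
    nrm <- sqrt(colSums(v^2))
    zero <- nrm < 1e-12
    nrm[zero] <- 1
    v <- sweep(v, 2L, nrm, "/")
    v[, zero] <- 0
    methods::new("ProcessedExpression",
        values = v, hvgIds = as.character(hvgIds),
        params = list(nHvgs = length(hvgIds), pseudocount = pseudocount,
                      theta = theta),
        zeroCells = unname(zero))
}

#' One-call preprocessing of a reference/query pair
#'
#' Selects HVGs on the reference (the labelled set; optionally on reference
#' and query jointly) and applies the shared log + L2 transform to both, so
#' the two processed matrices live on identical gene columns.
#'
#' @param reference,query datasets on the same gene universe.
#' @param nHvgs,pseudocount,theta see
#'   \code{\link{selectHvgsPearsonResiduals}} and
#'   \code{\link{logL2Normalize}}.
#' @param jointly select HVGs on the concatenated reference + query counts
#'   instead of the reference alone.
#' @return List with elements \code{reference} and \code{query}
#'   (\linkS4class{ProcessedExpression}) and \code{hvgIds}.
#' @export
preprocessPair <- function(reference, query, nHvgs = 1000,
                           pseudocount = 0.001, theta = 100,
                           jointly = FALSE) {
    shared <- intersect(geneIds(reference), geneIds(query))
    if (length(shared) == 0) stop("reference and query share no genes")
    ref <- reference[shared, ]
    qry <- query[shared, ]
    hvgSource <- if (jointly)
        concatenateDatasets(list(ref, qry), c("ref", "query")) else ref
    hvgs <- selectHvgsPearsonResiduals(hvgSource, nHvgs = nHvgs,
                                       theta = theta)
    list(reference = logL2Normalize(ref, hvgs, pseudocount, theta),
         query = logL2Normalize(qry, hvgs, pseudocount, theta),
         hvgIds = hvgs)
}

#' Accessors for processed expression
#'
#' @param x a \linkS4class{ProcessedExpression}.
#' @return \code{processedValues}: the genes x cells numeric matrix;
#'   \code{hvgIds}: the selected gene ids; \code{zeroCells}: logical flags
#'   for zero-norm cells.
#' @name processed-accessors
NULL

#' @rdname processed-accessors
#' @export
processedValues <- function(x) x@values

#' @rdname processed-accessors
#' @export
hvgIds <- function(x) x@hvgIds

#' @rdname processed-accessors
#' @export
zeroCells <- function(x) x@zeroCells

# Column subset of a ProcessedExpression (internal; used by subset series).
.subsetProcessed <- function(x, idx) {
    methods::new("ProcessedExpression",
        values = x@values[, idx, drop = FALSE],
        hvgIds = x@hvgIds, params = x@params,
        zeroCells = x@zeroCells[idx])
}
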