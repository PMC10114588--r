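#' Subsample a reference with a per-type cap
#'
#' Draws, uniformly without replacement and independently per cell type, at
#' most \code{cap} cells of every type; types with fewer cells than the cap
#' are kept in full, so the capped reference may remain unbalanced. Sampling
#' uses an independent substream per (seed, type name), so adding or removing
#' a type never changes another type's sample.
#'
#' @param dataset a labelled dataset.
#' @param cap maximum cells per cell type.
#' @param seed sampling seed.
#' @return A \linkS4class{ReferenceSubset} whose \code{cellIndices} point
#'   into the dataset's columns.
#' @export
subsampleReference <- function(dataset, cap, seed = 1L) {
    labels <- .requireLabels(dataset)
    cap <- .assertScalarCount(cap, "cap")
    idx <- integer(0)
    for (t in sort(unique(labels))) {
        cells <- which(labels == t)
        take <- min(cap, length(cells))
        picked <- if (take == length(cells)) cells else
            .withSeed(.deriveSeed(seed, "type", t),
                      sample(cells, take))
        idx <- c(idx, sort(picked))
    }
    methods::new("ReferenceSubset", cellIndices = idx, cap = cap,
                 seed = as.integer(seed),
                 parentId = "reference")
}

#' Accessors for reference subsets
#' @param x a \linkS4class{ReferenceSubset}.
#' @return \code{subsetIndices}: integer column indices; \code{subsetCap}:
#'   the per-type cap.
#' @name subset-accessors
NULL

#' @rdname subset-accessors
#' @export
subsetIndices <- function(x) x@cellIndices

#' @rdname subset-accessors
#' @export
subsetCap <- function(x) x@cap

#' Build the abundance-matched subset series of a reference
#'
#' The sampling design behind the weighted bootstrap: one subset per distinct
#' cell type, where the subset for type j is capped at type j's own abundance
#' in the full reference. The subset whose cap equals the largest abundance
#' is the full reference itself; the subset capped at the rarest type's
#' abundance is fully balanced.
#'
#' @param dataset a labelled dataset with at least 2 cell types.
#' @param seed sampling seed (per-subset substreams derived from it).
#' @return A \linkS4class{SubsetSeries}.
#' @examples
#' # abundances {A:1000, B:100, C:38} -> subsets capped at 1000, 100, 38
#' @export
buildSubsetSeries <- function(dataset, seed = 1L) {
    ab <- typeAbundances(dataset)
    if (length(ab) < 2L) stop("reference must contain at least 2 cell types")
    subsets <- lapply(seq_along(ab), function(j)
        subsampleReference(dataset, cap = ab[[j]],
                           seed = .deriveSeed(seed, "series", j)))
    methods::new("SubsetSeries", subsets = subsets,
                 caps = as.integer(ab), typeNames = names(ab))
}

#' Assemble a mosaic reference from multiple sources
#'
#' Concatenates labelled datasets from different sources/technologies into
#' one reference on their shared gene universe, with no batch correction.
#' The gene universe is the intersection by default (avoiding imputed zeros
#' for genes a protocol never measured) in canonical sorted order; set
#' \code{genePolicy = "union"} to keep all genes with zeros filled in.
#' Per-type abundances add up across sources; the resulting abundance table
#' is attached as metadata (\code{abundanceReport}).
#'
#' @param datasets list of labelled datasets.
#' @param batchNames one source name per dataset.
#' @param genePolicy \code{"intersection"} (default) or \code{"union"}.
#' @return A combined labelled dataset.
#' @export
assembleMosaic <- function(datasets, batchNames,
                           genePolicy = c("intersection", "union")) {
    genePolicy <- match.arg(genePolicy)
    stopifnot(length(datasets) >= 1L,
              length(batchNames) == length(datasets))
    for (d in datasets) .requireLabels(d)
    geneSets <- lapply(datasets, geneIds)
    genes <- if (genePolicy == "intersection")
        sort(Reduce(intersect, geneSets)) else sort(Reduce(union, geneSets))
    if (length(genes) == 0L) stop("datasets share no genes")
    aligned <- lapply(datasets, function(d) {
        if (identical(geneIds(d), genes)) return(d)
        counts <- SummarizedExperiment::assay(d, "counts")
        if (all(genes %in% rownames(counts))) {
            counts <- counts[genes, , drop = FALSE]
        } else {
            full <- Matrix::Matrix(0, nrow = length(genes),
                                   ncol = ncol(counts), sparse = TRUE,
                                   dimnames = list(genes, colnames(counts)))
            present <- intersect(genes, rownames(counts))
            full[present, ] <- counts[present, ]
            counts <- full
        }
        ExpressionDataset(counts, geneIds = genes, cellIds = cellIds(d),
                          labels = cellLabels(d))
    })
    mosaic <- concatenateDatasets(aligned, batchNames)
    S4Vectors::metadata(mosaic)$abundanceReport <- typeAbundances(mosaic)
    mosaic
}

#' Sweep the per-type cap and score every cell type
#'
#' For every cap and permutation, subsamples the reference with that cap,
#' classifies the query against the subsample, and scores each cell type;
#' the experiment behind the rule of thumb that a cell type is
#' predicted best when the cap is closest to its own abundance. Preprocessing
#' (HVG selection on the full reference) is shared across all runs so the
#' sweep isolates the sampling effect.
#'
#' @param dataset labelled reference dataset.
#' @param query labelled query dataset (ground truth needed for scoring).
#' @param spec a \linkS4class{ClassifierSpec}.
#' @param caps integer vector of caps; the conventional sweep preset is
#'   \code{defaultCapSweep()}.
#' @param nPerm permutations per cap (default 20).
#' @param seed base seed.
#' @param nHvgs,pseudocount,theta preprocessing parameters.
#' @return Tidy data.frame with columns \code{cap}, \code{perm},
#'   \code{cell_type}, \code{accuracy}, \code{precision}, \code{f1}
#'   (one row per cap x permutation x cell type).
#' @export
sweepCaps <- function(dataset, query, spec, caps = defaultCapSweep(),
                      nPerm = 20L, seed = 1L, nHvgs = 1000,
                      pseudocount = 0.001, theta = 100) {
    stopifnot(length(caps) >= 1L, nPerm >= 1L)
    truth <- .requireLabels(query)
    proc <- preprocessPair(dataset, query, nHvgs = nHvgs,
                           pseudocount = pseudocount, theta = theta)
    refLabels <- .requireLabels(dataset)
    out <- list()
    for (cap in caps) {
        for (perm in seq_len(nPerm)) {
            sub <- subsampleReference(dataset, cap = cap,
                                      seed = .deriveSeed(seed, cap, perm))
            idx <- subsetIndices(sub)
            pred <- predictLabels(spec,
                                  .subsetProcessed(proc$reference, idx),
                                  refLabels[idx], proc$query)
            rep_ <- evaluateLabels(pred, data.frame(
                cell_id = cellIds(query), label = truth,
                stringsAsFactors = FALSE))
            pc <- perClassMetrics(rep_)
            out[[length(out) + 1L]] <- data.frame(
                cap = cap, perm = perm, cell_type = pc$cell_type,
                accuracy = pc$accuracy, precision = pc$precision,
                f1 = pc$f1, stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}

#' Conventional cap-sweep preset
#'
#' The standard list of per-type caps used for reference sampling sweeps:
#' 38, 100, 250, 500, 1000, 1500, 2000, 3000 cells per type.
#'
#' @return Integer vector of caps.
#' @export
defaultCapSweep <- function()
    c(38L, 100L, 250L, 500L, 1000L, 1500L, 2000L, 3000L)
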