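#' Describe a synthetic imbalanced scRNA-seq dataset
#'
#' Builds the generative description consumed by
#' \code{\link{generateSynthetic}}: K planted cell types with chosen
#' abundances, per-type marker genes up-regulated by a multiplicative fold,
#' optional closely related type pairs that share a fraction of their markers
#' at full fold, a lognormal per-gene baseline, per-cell lognormal library
#' size factors, negative-binomial counts with overdispersion theta
#' (variance = mu + mu^2/theta), and optional multi-batch structure with
#' multiplicative lognormal per-(batch, gene) effects.
#'
#' The master \code{seed} fixes the gene-level structure (baseline means,
#' marker map, batch factors); cell-level sampling can be re-drawn with a
#' different seed to produce a matched query set from the same underlying
#' model (see \code{generateSynthetic}).
#'
#' @param cellTypes data.frame with columns \code{name}, \code{abundance}.
#' @param nGenes number of genes.
#' @param markersPerType markers per type.
#' @param markerFold multiplicative marker up-regulation (> 1).
#' @param relatedPairs data.frame with \code{typeA}, \code{typeB},
#'   \code{sharedFraction}; pairs share that fraction of their markers.
#' @param baselineMeanLogdist (meanlog, sdlog) of the per-gene lognormal
#'   baseline mean.
#' @param dispersion NB overdispersion theta of the simulator.
#' @param libsizeLogdist (meanlog, sdlog) of per-cell library factors.
#' @param batches data.frame with \code{name}, \code{fraction},
#'   \code{batchEffectSigma} (sdlog of the per-(batch, gene) factor).
#' @param seed master seed.
#' @return A \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(cellTypes, nGenes = 2000L, markersPerType = 20L,
                          markerFold = 6,
                          relatedPairs = data.frame(typeA = character(),
                                                    typeB = character(),
                                                    sharedFraction = numeric()),
                          baselineMeanLogdist = c(log(0.5), 1.2),
                          dispersion = 10,
                          libsizeLogdist = c(0, 0.35),
                          batches = data.frame(name = "batch1", fraction = 1,
                                               batchEffectSigma = 0),
                          seed = 1L) {
    methods::new("SyntheticSpec",
        cellTypes = data.frame(name = as.character(cellTypes$name),
                               abundance = as.integer(cellTypes$abundance),
                               stringsAsFactors = FALSE),
        nGenes = as.integer(nGenes),
        markersPerType = as.integer(markersPerType),
        markerFold = as.numeric(markerFold),
        relatedPairs = relatedPairs,
        baselineMeanLogdist = as.numeric(baselineMeanLogdist),
        dispersion = as.numeric(dispersion),
        libsizeLogdist = as.numeric(libsizeLogdist),
        batches = batches,
        seed = as.integer(seed))
}

# Gene-level structure shared by every draw from a spec: baseline means,
# marker map (with related-pair sharing), per-(batch, gene) factors.
.geneModel <- function(spec) {
    .withSeed(.deriveSeed(spec@seed, "gene-model"), {
        K <- nrow(spec@cellTypes)
        m <- spec@markersPerType
        genes <- sprintf("gene%04d", seq_len(spec@nGenes))
        baseline <- rlnorm(spec@nGenes, spec@baselineMeanLogdist[1],
                           spec@baselineMeanLogdist[2])
        names(baseline) <- genes
        # markers: disjoint random gene blocks per type, then sharing
        markerPool <- sample(spec@nGenes, K * m)
        markerMap <- split(genes[markerPool],
                           rep(spec@cellTypes$name, each = m))
        markerMap <- markerMap[spec@cellTypes$name]
        rp <- spec@relatedPairs
        if (nrow(rp) > 0) {
            for (i in seq_len(nrow(rp))) {
                nShared <- round(rp$sharedFraction[i] * m)
                if (nShared > 0) {
                    shared <- markerMap[[rp$typeA[i]]][seq_len(nShared)]
                    own <- markerMap[[rp$typeB[i]]]
                    markerMap[[rp$typeB[i]]] <-
                        c(shared, own[seq_len(m - nShared)])
                }
            }
        }
        fold <- matrix(1, nrow = spec@nGenes, ncol = K,
                       dimnames = list(genes, spec@cellTypes$name))
        for (t in spec@cellTypes$name)
            fold[markerMap[[t]], t] <- spec@markerFold
        batchFactor <- matrix(1, nrow = spec@nGenes,
                              ncol = nrow(spec@batches),
                              dimnames = list(genes, spec@batches$name))
        for (b in seq_len(nrow(spec@batches))) {
            s <- spec@batches$batchEffectSigma[b]
            if (s > 0)
                batchFactor[, b] <- rlnorm(spec@nGenes, 0, s)
        }
        list(genes = genes, baseline = baseline, markerMap = markerMap,
             fold = fold, batchFactor = batchFactor)
    })
}

#' Generate a synthetic dataset with ground truth
#'
#' Draws counts \eqn{x_{gc} \sim NB(\mu_{gc}, \theta)} with
#' \eqn{\mu_{gc} = s_c \, b_g \, f_{t(c),g} \, e_{batch(c),g}}: per-cell
#' library factor, lognormal gene baseline, marker fold for the cell's own
#' type (shared markers for related pairs), and a multiplicative batch
#' factor. Gene-level structure is fixed by the spec's master seed, so two
#' draws with different \code{cellSeed}s (e.g. a reference and a query) come
#' from the same underlying cell type model with the same marker genes.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param cellSeed seed for the cell-level draw; defaults to the spec seed,
#'   making \code{generateSynthetic(spec)} fully reproducible.
#' @param abundances optional named integer vector overriding the per-type
#'   cell numbers (names must be spec cell types); used to draw smaller or
#'   larger query sets from the same model.
#' @param idPrefix prefix for generated cell ids.
#' @return A list with \code{dataset} (labelled dataset), \code{markerMap}
#'   (type -> marker gene ids) and \code{batchMap} (cell id -> batch).
#' @examples
#' spec <- syntheticSpec(data.frame(name = c("A", "B"),
#'                                  abundance = c(50, 30)),
#'                       nGenes = 100, markersPerType = 5, seed = 7)
#' bundle <- generateSynthetic(spec)
#' typeAbundances(bundle$dataset)
#' @export
generateSynthetic <- function(spec, cellSeed = NULL, abundances = NULL,
                              idPrefix = "cell") {
    methods::validObject(spec)
    gm <- .geneModel(spec)
    if (is.null(cellSeed)) cellSeed <- spec@seed
    ab <- setNames(spec@cellTypes$abundance, spec@cellTypes$name)
    if (!is.null(abundances)) {
        if (!all(names(abundances) %in% names(ab)))
            stop("abundance override names unknown cell types")
        ab[names(abundances)] <- as.integer(abundances)
    }
    nCells <- sum(ab)
    types <- rep(names(ab), ab)
    # deterministic batch assignment by fractions, interleaved across types
    nBatches <- nrow(spec@batches)
    batchOf <- if (nBatches == 1L) rep(spec@batches$name, nCells) else {
        cuts <- round(cumsum(spec@batches$fraction) * nCells)
        rep(spec@batches$name, diff(c(0L, cuts)))
    }
    .withSeed(.deriveSeed(cellSeed, "cells"), {
        libFactor <- rlnorm(nCells, spec@libsizeLogdist[1],
                            spec@libsizeLogdist[2])
        counts <- matrix(0L, nrow = spec@nGenes, ncol = nCells)
        for (grp in split(seq_len(nCells),
                          paste(types, batchOf, sep = "\r"))) {
            t <- types[grp[1L]]
            b <- batchOf[grp[1L]]
            geneMean <- gm$baseline * gm$fold[, t] * gm$batchFactor[, b]
            mu <- outer(geneMean, libFactor[grp])
            counts[, grp] <- rnbinom(length(mu), mu = mu,
                                     size = spec@dispersion)
        }
        ids <- sprintf("%s%05d", idPrefix, seq_len(nCells))
        ds <- ExpressionDataset(counts, geneIds = gm$genes, cellIds = ids,
                                labels = types, batch = batchOf)
        S4Vectors::metadata(ds)$markerMap <- gm$markerMap
        list(dataset = ds, markerMap = gm$markerMap,
             batchMap = setNames(batchOf, ids))
    })
}

#' PBMC-like imbalanced preset
#'
#' Nine cell types with strongly imbalanced abundances
#' (3000, 2500, 1500, 1000, 600, 300, 150, 60, 38 cells; 9148 in total),
#' 2000 genes, 20 markers per type at fold 6, and one closely related pair:
#' the rarest type shares half of its markers with an abundant type,
#' emulating the hard rare-type/abundant-type boundaries seen in real PBMC
#' annotations. Single batch.
#'
#' @param seed master seed.
#' @return A \linkS4class{SyntheticSpec}.
#' @export
presetPbmcLike <- function(seed = 1L) {
    ab <- c(3000L, 2500L, 1500L, 1000L, 600L, 300L, 150L, 60L, 38L)
    nm <- sprintf("type%02d_n%d", seq_along(ab), ab)
    syntheticSpec(
        cellTypes = data.frame(name = nm, abundance = ab),
        nGenes = 2000L, markersPerType = 20L, markerFold = 6,
        relatedPairs = data.frame(typeA = nm[3L], typeB = nm[9L],
                                  sharedFraction = 0.5),
        seed = seed)
}

#' Mosaic multi-source preset
#'
#' Three sources sharing cell types and marker genes but carrying independent
#' multiplicative batch effects (sdlog \code{batchEffectSigma}, default 0.3)
#' and different per-type abundances; the rarest type grows from 38 cells in
#' the main source to roughly triple that when pooled, the situation in which
#' assembling a mosaic reference pays off.
#'
#' @param seed master seed (shared, so all sources share the gene model).
#' @param batchEffectSigma sdlog of the per-(source, gene) factor.
#' @return A list of three \linkS4class{SyntheticSpec}s, one per source. Each
#'   spec describes all three batches but a source generates only its own
#'   cells; use \code{\link{generateSyntheticMosaic}} to draw them.
#' @export
presetMosaic <- function(seed = 1L, batchEffectSigma = 0.3) {
    base <- presetPbmcLike(seed)
    nm <- base@cellTypes$name
    abundBySource <- list(
        source1 = base@cellTypes$abundance,
        source2 = c(1000L, 800L, 500L, 350L, 200L, 100L, 60L, 40L, 32L),
        source3 = c(800L, 600L, 400L, 250L, 150L, 80L, 40L, 30L, 32L))
    batches <- data.frame(name = names(abundBySource),
                          fraction = c(1, 0, 0),
                          batchEffectSigma = batchEffectSigma)
    lapply(names(abundBySource), function(src) {
        b <- batches
        b$fraction <- as.numeric(b$name == src)
        syntheticSpec(
            cellTypes = data.frame(name = nm,
                                   abundance = abundBySource[[src]]),
            nGenes = base@nGenes, markersPerType = base@markersPerType,
            markerFold = base@markerFold, relatedPairs = base@relatedPairs,
            baselineMeanLogdist = base@baselineMeanLogdist,
            dispersion = base@dispersion,
            libsizeLogdist = base@libsizeLogdist,
            batches = b, seed = seed)
    })
}

#' Draw all sources of a mosaic preset
#'
#' @param specs list of specs as returned by \code{\link{presetMosaic}}.
#' @param cellSeed cell-level seed (per-source substreams derived from it).
#' @return List of ground-truth bundles, one per source.
#' @export
generateSyntheticMosaic <- function(specs, cellSeed = NULL) {
    lapply(seq_along(specs), function(i) {
        cs <- if (is.null(cellSeed)) specs[[i]]@seed else cellSeed
        generateSynthetic(specs[[i]],
                          cellSeed = .deriveSeed(cs, "source", i),
                          idPrefix = sprintf("s%dcell", i))
    })
}
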