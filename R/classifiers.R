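#' Describe a label transfer classifier
#'
#' Uniform description of the classifier algorithms the package implements,
#' so that reference-design experiments and the weighted bootstrap are
#' classifier-agnostic. Available algorithms:
#' \describe{
#'   \item{\code{centroid}}{per-type centroid of the processed reference;
#'     query cells take the label of the most Pearson-correlated centroid.
#'     Fast baseline. Params: \code{tau} (softmax temperature for the
#'     confidence, default 10).}
#'   \item{\code{singler_like}}{iterative Spearman-correlation elimination:
#'     per query cell, correlate against every reference cell on genes that
#'     discriminate the surviving types, aggregate per type, drop the lowest
#'     type and every type more than \code{margin} below the top, repeat
#'     until two types remain, predict the higher. Params: \code{margin}
#'     (0.05), \code{genesPerType} (50), \code{aggregate} ("quantile" or
#'     "mean"), \code{quantileProb} (0.8).}
#'   \item{\code{cca_mnn}}{canonical-correlation embedding of reference and
#'     query into a shared space (SVD of the cross-product of the two
#'     gene-standardized matrices) followed by mutual-nearest-neighbor label
#'     voting. Params: \code{nCca} (20), \code{k} (5).}
#'   \item{\code{toppair_forest}}{top-pair transform (binary gene-vs-gene
#'     comparisons on discriminative pairs) followed by a random forest;
#'     optionally trains an extra class of shuffled-expression random
#'     profiles whose predictions are emitted as
#'     \code{\link{unassignedLabel}}. Params: \code{nTopGenes} (25),
#'     \code{maxPairs} (250), \code{numTrees} (200), \code{nRand} (0).}
#' }
#'
#' @param name algorithm name.
#' @param params method-specific overrides, see above.
#' @param seed integer seed for stochastic components.
#' @return A \linkS4class{ClassifierSpec}.
#' @examples
#' classifierSpec("centroid")
#' classifierSpec("singler_like", params = list(margin = 0.1), seed = 3)
#' @export
classifierSpec <- function(name, params = list(), seed = 1L) {
    defaults <- switch(name,
        centroid = list(tau = 10),
        singler_like = list(margin = 0.05, genesPerType = 50,
                            aggregate = "quantile", quantileProb = 0.8),
        cca_mnn = list(nCca = 20, k = 5),
        toppair_forest = list(nTopGenes = 25, maxPairs = 250,
                              numTrees = 200, nRand = 0),
        stop(sprintf("unknown classifier '%s'", name)))
    bad <- setdiff(names(params), names(defaults))
    if (length(bad))
        stop(sprintf("unknown params for %s: %s", name,
                     paste(bad, collapse = ", ")))
    defaults[names(params)] <- params
    methods::new("ClassifierSpec", name = name, params = defaults,
                 seed = as.integer(seed))
}

#' Predict query cell type labels with a classifier
#'
#' Runs the classifier described by \code{spec} on processed reference and
#' query matrices sharing the same gene panel. Zero-norm query cells (see
#' \code{\link{logL2Normalize}}) are always emitted as
#' \code{\link{unassignedLabel}} with confidence 0, whatever the classifier.
#' All classifiers break ties by lexicographic label order and are invariant
#' to the order of reference cells.
#'
#' @param spec a \linkS4class{ClassifierSpec}.
#' @param reference a \linkS4class{ProcessedExpression} for the reference.
#' @param refLabels character, one label per reference cell.
#' @param query a \linkS4class{ProcessedExpression} for the query.
#' @return data.frame with columns \code{cell_id}, \code{label},
#'   \code{confidence} (in [0, 1]), one row per query cell, in query order.
#' @export
predictLabels <- function(spec, reference, refLabels, query) {
    stopifnot(methods::is(spec, "ClassifierSpec"),
              methods::is(reference, "ProcessedExpression"),
              methods::is(query, "ProcessedExpression"))
    if (!identical(reference@hvgIds, query@hvgIds))
        stop("reference and query must share the same gene columns")
    refLabels <- as.character(refLabels)
    if (length(refLabels) != ncol(reference@values))
        stop("refLabels must have one entry per reference cell")
    nLab <- length(unique(refLabels))
    if (spec@name != "centroid" && nLab < 2)
        stop("reference must contain at least 2 distinct labels")
    qIds <- colnames(query@values)
    out <- data.frame(cell_id = qIds,
                      label = rep(unassignedLabel(), length(qIds)),
                      confidence = rep(0, length(qIds)),
                      stringsAsFactors = FALSE)
    live <- !query@zeroCells
    # drop zero-norm reference cells: they carry no signal
    refKeep <- !reference@zeroCells
    if (!any(refKeep)) stop("reference contains only zero-norm cells")
    ref <- .subsetProcessed(reference, which(refKeep))
    labs <- refLabels[refKeep]
    if (any(live)) {
        qry <- .subsetProcessed(query, which(live))
        fun <- switch(spec@name,
            centroid = .predictCentroid,
            singler_like = .predictSinglerLike,
            cca_mnn = .predictCcaMnn,
            toppair_forest = .predictToppairForest)
        res <- fun(ref, labs, qry, spec@params, spec@seed)
        out$label[live] <- res$label
        out$confidence[live] <- pmin(pmax(res$confidence, 0), 1)
    }
    out
}

# ---- centroid ---------------------------------------------------------------

.predictCentroid <- function(ref, refLabels, qry, params, seed) {
    types <- sort(unique(refLabels))
    cent <- vapply(types, function(t)
        rowMeans(ref@values[, refLabels == t, drop = FALSE]),
        numeric(nrow(ref@values)))
    cors <- .colCor(cent, qry@values)            # types x query cells
    tau <- params$tau
    label <- character(ncol(cors))
    conf <- numeric(ncol(cors))
    for (j in seq_len(ncol(cors))) {
        s <- setNames(cors[, j], types)
        win <- .argmaxLabel(s)
        p <- exp((s - max(s)) * tau)
        label[j] <- win
        conf[j] <- p[win] / sum(p)
    }
    list(label = label, confidence = conf)
}

# ---- iterative Spearman elimination ----------------------------------------

# Discriminative genes among the surviving types: per type, rank genes by
# (that type's median log-expression) - (max median among the other
# surviving types), take the top m, union over types.
.singlerGenes <- function(medians, surviving, m) {
    sub <- medians[, surviving, drop = FALSE]
    picked <- integer(0)
    for (t in surviving) {
        others <- sub[, setdiff(surviving, t), drop = FALSE]
        maxOther <- others[, 1L]
        for (j in seq_len(ncol(others))[-1L])
            maxOther <- pmax(maxOther, others[, j])
        score <- sub[, t] - maxOther
        ord <- order(-score, rownames(medians))
        picked <- c(picked, ord[seq_len(min(m, length(ord)))])
    }
    sort(unique(picked))
}

.aggregateScores <- function(corMat, refTypes, surviving, params) {
    # corMat: ref cells x query cells; returns types x query cells
    out <- matrix(NA_real_, nrow = length(surviving), ncol = ncol(corMat),
                  dimnames = list(surviving, NULL))
    for (t in surviving) {
        rows <- corMat[refTypes == t, , drop = FALSE]
        out[t, ] <- if (nrow(rows) == 0L) -1       # type absent: floor score
        else if (identical(params$aggregate, "mean")) colMeans(rows)
        else .colQuantiles(rows, params$quantileProb)
    }
    out
}

.singlerMedians <- function(X, refLabels) {
    types <- sort(unique(refLabels))
    md <- vapply(types, function(t)
        .rowMedians(X, which(refLabels == t)), numeric(nrow(X)))
    rownames(md) <- rownames(X)
    md
}

# One elimination/finalization step for a block of query cells sharing a
# surviving set. Mutates the state environment (active/done/label/conf/
# sMinFirst vectors indexed by query cell).
.singlerStep <- function(state, cells, surviving, scores, K, margin) {
    if (length(surviving) == K)
        state$sMinFirst[cells] <- apply(scores, 2L, min)
    if (length(surviving) == 2L) {
        for (idx in seq_along(cells)) {
            s <- setNames(scores[, idx], surviving)
            win <- .argmaxLabel(s)
            s1 <- max(s)
            s2 <- min(s)
            floorScore <- min(state$sMinFirst[cells[idx]], s2, na.rm = TRUE)
            state$conf[cells[idx]] <- min(1, max(0,
                (s1 - s2) / max(s1 - floorScore, 1e-8)))
            state$label[cells[idx]] <- win
        }
        state$done[cells] <- TRUE
    } else {
        for (idx in seq_along(cells)) {
            s <- setNames(scores[, idx], surviving)
            dropOne <- surviving[order(s, surviving)][1L]
            keep <- surviving[s >= max(s) - margin]
            keep <- setdiff(keep, dropOne)
            if (length(keep) < 2L)
                keep <- surviving[order(-s, surviving)][1:2]
            state$active[[cells[idx]]] <- sort(keep)
        }
    }
    invisible(NULL)
}

# Batched iterative Spearman elimination over several reference column
# subsets of one shared matrix (the bootstrap's subset series plus the full
# reference). All runs share discriminative gene sets derived from
# `medians`, so within each round every distinct surviving set is ranked
# and standardized exactly once, however many runs need it; each run then
# takes its own columns out of the shared rank matrix. Results for any
# single run are identical to running it alone.
#
# X: genes x cells shared reference matrix; runCols: list of column index
# vectors, one per run; Y: genes x query cells. Returns one
# list(label, confidence) per run.
.singlerBatch <- function(X, refLabels, runCols, Y, params, medians) {
    types <- sort(unique(refLabels))
    K <- length(types)
    m <- params$genesPerType
    margin <- params$margin
    nq <- ncol(Y)
    nRuns <- length(runCols)
    states <- lapply(seq_len(nRuns), function(r) {
        st <- new.env(parent = emptyenv())
        st$active <- rep(list(types), nq)
        st$done <- logical(nq)
        st$label <- character(nq)
        st$conf <- numeric(nq)
        st$sMinFirst <- rep(NA_real_, nq)
        st
    })
    repeat {
        # group (run, query cells) pairs by surviving set across all runs
        tasks <- list()
        for (r in seq_len(nRuns)) {
            st <- states[[r]]
            if (all(st$done)) next
            keys <- vapply(st$active, paste, character(1), collapse = "\r")
            keys[st$done] <- NA
            for (key in unique(keys[!st$done])) {
                cells <- which(!st$done & keys == key)
                tasks[[key]] <- c(tasks[[key]],
                                  list(list(run = r, cells = cells)))
            }
        }
        if (length(tasks) == 0L) break
        for (key in names(tasks)) {
            surviving <- strsplit(key, "\r", fixed = TRUE)[[1L]]
            genes <- .singlerGenes(medians, surviving, m)
            colsFull <- which(refLabels %in% surviving)
            Rall <- .standardizeCols(
                .colRanks(X[genes, colsFull, drop = FALSE]))
            unionCells <- sort(unique(unlist(
                lapply(tasks[[key]], `[[`, "cells"))))
            Rq <- .standardizeCols(
                .colRanks(Y[genes, unionCells, drop = FALSE]))
            for (task in tasks[[key]]) {
                st <- states[[task$run]]
                sel <- runCols[[task$run]]
                sel <- sel[refLabels[sel] %in% surviving]
                pos <- match(sel, colsFull)
                corMat <- crossprod(Rall[, pos, drop = FALSE],
                                    Rq[, match(task$cells, unionCells),
                                       drop = FALSE])
                scores <- .aggregateScores(corMat, refLabels[sel],
                                           surviving, params)
                .singlerStep(st, task$cells, surviving, scores, K, margin)
            }
        }
    }
    lapply(states, function(st)
        list(label = st$label, confidence = st$conf))
}

.predictSinglerLike <- function(ref, refLabels, qry, params, seed) {
    X <- ref@values
    medians <- .singlerMedians(X, refLabels)
    .singlerBatch(X, refLabels, list(seq_len(ncol(X))), qry@values,
                  params, medians)[[1L]]
}

# ---- CCA + mutual nearest neighbors ----------------------------------------

.predictCcaMnn <- function(ref, refLabels, qry, params, seed) {
    if (params$nCca < 1) stop("nCca must be >= 1")
    X <- ref@values
    Y <- qry@values
    # per-gene standardization within each dataset
    Xs <- t(.standardizeCols(t(X)))
    Ys <- t(.standardizeCols(t(Y)))
    cp <- crossprod(Xs, Ys)                      # ref cells x query cells
    d <- max(1L, min(params$nCca, nrow(cp), ncol(cp), nrow(X)))
    sv <- svd(cp, nu = d, nv = d)
    if (max(sv$d) < 1e-12)
        stop("degenerate cross-product: no shared correlation structure")
    # scale components by their singular values so uninformative trailing
    # components cannot dominate after the row normalization below
    sw <- sv$d[seq_len(d)] / sv$d[1L]
    embedR <- sweep(sv$u, 2L, sw, "*")
    embedQ <- sweep(sv$v, 2L, sw, "*")
    l2 <- function(m) {
        n <- sqrt(rowSums(m^2))
        n[n < 1e-12] <- 1
        m / n
    }
    embedR <- l2(embedR)
    embedQ <- l2(embedQ)
    # full distance matrix (ref x query); k nearest in both directions
    d2 <- outer(rowSums(embedR^2), rowSums(embedQ^2), "+") -
        2 * tcrossprod(embedR, embedQ)
    k <- params$k
    nR <- nrow(d2)
    nQ <- ncol(d2)
    kq <- min(k, nR)
    kr <- min(k, nQ)
    nnOfQuery <- apply(d2, 2L, function(col)
        order(col)[seq_len(kq)])                  # kq x nQ
    nnOfQuery <- matrix(nnOfQuery, nrow = kq)
    nnOfRef <- apply(d2, 1L, function(row)
        order(row)[seq_len(kr)])                  # kr x nR
    nnOfRef <- matrix(nnOfRef, nrow = kr)
    label <- character(nQ)
    conf <- numeric(nQ)
    for (j in seq_len(nQ)) {
        cand <- nnOfQuery[, j]
        mutual <- cand[vapply(cand, function(i) j %in% nnOfRef[, i],
                              logical(1))]
        if (length(mutual) == 0L) {
            label[j] <- refLabels[order(d2[, j])[1L]]
            conf[j] <- 0
        } else {
            votes <- table(refLabels[mutual])
            s <- setNames(as.numeric(votes), names(votes))
            win <- .argmaxLabel(s)
            label[j] <- win
            conf[j] <- s[win] / length(mutual)
        }
    }
    list(label = label, confidence = conf)
}

# ---- top-pair transform + random forest ------------------------------------

.toppairPairs <- function(X, refLabels, nTopGenes, maxPairs) {
    types <- sort(unique(refLabels))
    diffs <- vapply(types, function(t) {
        inT <- refLabels == t
        rowMeans(X[, inT, drop = FALSE]) -
            rowMeans(X[, !inT, drop = FALSE])
    }, numeric(nrow(X)))
    topOf <- apply(diffs, 2L, function(s)
        order(-s, rownames(X))[1L])              # best gene per type
    names(topOf) <- types
    pairs <- matrix(integer(0), ncol = 2L)
    seen <- character(0)
    for (r in seq_len(nTopGenes)) {              # breadth-first over ranks
        for (t in types) {
            ord <- order(-diffs[, t], rownames(X))
            if (r > length(ord)) next
            g1 <- ord[r]
            for (t2 in setdiff(types, t)) {
                g2 <- topOf[[t2]]
                if (g1 == g2) next
                key <- paste(min(g1, g2), max(g1, g2))
                if (key %in% seen) next
                seen <- c(seen, key)
                pairs <- rbind(pairs, c(g1, g2))
                if (nrow(pairs) >= maxPairs) return(pairs)
            }
        }
    }
    pairs
}

.toppairEncode <- function(X, pairs) {
    # cells x pairs binary matrix
    enc <- t(X[pairs[, 1L], , drop = FALSE] > X[pairs[, 2L], , drop = FALSE])
    storage.mode(enc) <- "double"
    colnames(enc) <- paste0("p", seq_len(nrow(pairs)))
    enc
}

.predictToppairForest <- function(ref, refLabels, qry, params, seed) {
    # canonical training order (label, then cell id) so the forest is
    # invariant to the order reference cells arrive in
    ord <- order(refLabels, colnames(ref@values))
    X <- ref@values[, ord, drop = FALSE]
    refLabels <- refLabels[ord]
    pairs <- .toppairPairs(X, refLabels, params$nTopGenes, params$maxPairs)
    if (nrow(pairs) == 0L)
        stop("no gene pairs selectable (fewer than 2 distinct genes?)")
    randomClass <- ".random_profile"
    trainX <- .toppairEncode(X, pairs)
    trainY <- refLabels
    if (params$nRand > 0) {
        randX <- .withSeed(.deriveSeed(seed, "random-profiles"), {
            vapply(seq_len(nrow(X)), function(g)
                sample(X[g, ], params$nRand, replace = TRUE),
                numeric(params$nRand))
        })                                        # nRand x genes
        randEnc <- .toppairEncode(t(randX), pairs)
        trainX <- rbind(trainX, randEnc)
        trainY <- c(trainY, rep(randomClass, params$nRand))
    }
    df <- as.data.frame(trainX)
    df$.label <- factor(trainY)
    # inverse-frequency class weights: an imbalanced reference must not let
    # the forest's prior swallow the rare types
    freq <- table(df$.label)[levels(df$.label)]
    cw <- as.numeric(1 / freq)
    cw <- cw / mean(cw)
    fit <- ranger::ranger(dependent.variable.name = ".label", data = df,
                          num.trees = params$numTrees, probability = TRUE,
                          seed = .deriveSeed(seed, "forest"),
                          class.weights = cw,
                          num.threads = 1L)
    testDf <- as.data.frame(.toppairEncode(qry@values, pairs))
    probs <- stats::predict(fit, data = testDf,
                            num.threads = 1L)$predictions
    label <- character(nrow(testDf))
    conf <- numeric(nrow(testDf))
    for (j in seq_len(nrow(probs))) {
        s <- setNames(as.numeric(probs[j, ]), colnames(probs))
        win <- .argmaxLabel(s)
        conf[j] <- s[win]
        label[j] <- if (win == randomClass) unassignedLabel() else win
    }
    list(label = label, confidence = conf)
}
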