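#' Vote weight of a predicted label in an abundance-capped subset
#'
#' The heart of the weighted bootstrap-annotation scheme: a prediction made
#' on a reference subset capped at \code{cap} cells per type is weighted by
#' how close the predicted label's abundance in the \emph{full} reference,
#' \code{nLabel}, is to that cap,
#' \deqn{w = \frac{1}{|n(l) - max(r_j)| + 1},}
#' so a label votes at full weight (w = 1) exactly in the subset whose cap
#' matches its abundance and with strictly decreasing weight as the mismatch
#' grows. The weight is symmetric in its two arguments and always lies in
#' (0, 1].
#'
#' With \code{strict = TRUE} the absolute value is dropped
#' (\eqn{w = 1/(n(l) - max(r_j) + 1)}), which is only well defined when
#' \eqn{n(l) \ge max(r_j)}; non-positive denominators raise an error. The
#' default symmetric form is the one used throughout the package.
#'
#' @param nLabel abundance of the predicted label in the full reference
#'   (vectorized).
#' @param cap per-type cap of the subset the vote came from (vectorized).
#' @param strict use the asymmetric form without the absolute value.
#' @return Numeric weights in (0, 1].
#' @examples
#' computeWeight(500, 500)    # 1
#' computeWeight(109, 100)    # 1/10
#' computeWeight(38, 1000)    # 1/963
#' @export
computeWeight <- function(nLabel, cap, strict = FALSE) {
    if (any(nLabel < 1) || any(cap < 1))
        stop("nLabel and cap must be positive")
    if (strict) {
        den <- nLabel - cap + 1
        if (any(den <= 0))
            stop("strict weight undefined: n(label) - cap + 1 must be positive")
        return(1 / den)
    }
    1 / (abs(nLabel - cap) + 1)
}

#' Weighted bootstrap-annotation of a query dataset
#'
#' Runs the full scheme: for each of \code{nBoot} replicates, build the
#' abundance-matched subset series of the reference
#' (\code{\link{buildSubsetSeries}}), classify the query against every
#' subset, and weight each per-cell vote by
#' \code{\link{computeWeight}(n(label in full reference), cap of the
#' subset)}. Weights are summed per label over all subsets and replicates
#' and each cell receives the label with the highest total (ties broken
#' lexicographically). Unassigned votes carry zero weight and can never win;
#' a cell all of whose votes are unassigned is emitted as
#' \code{\link{unassignedLabel}}. The reported confidence is the bootstrap
#' stability: the winning label's share of the cell's total vote weight.
#'
#' Preprocessing (HVG selection on the full reference, log + L2 transform)
#' happens once; subsets are column subsets of the processed reference.
#' Replicate r uses seed \code{seed + r - 1}.
#'
#' @param query query dataset.
#' @param reference labelled reference dataset (>= 2 cell types).
#' @param spec a \linkS4class{ClassifierSpec}.
#' @param nBoot number of independent subset-series replicates (default 20).
#' @param seed base seed.
#' @param nHvgs,pseudocount,theta preprocessing parameters.
#' @param strict use the strict (asymmetric) weight form.
#' @param processed optional precomputed result of
#'   \code{\link{preprocessPair}(reference, query, ...)} to reuse across
#'   runs.
#' @param .extraRuns internal: extra reference column subsets predicted in
#'   the same batch (their predictions are attached as the
#'   \code{"extraPredictions"} attribute).
#' @return A \linkS4class{BootstrapResult}.
#' @export
runWeightedBootstrap <- function(query, reference, spec, nBoot = 20L,
                                 seed = 1L, nHvgs = 1000,
                                 pseudocount = 0.001, theta = 100,
                                 strict = FALSE, processed = NULL,
                                 .extraRuns = NULL) {
    nBoot <- .assertScalarCount(nBoot, "nBoot")
    refLabels <- .requireLabels(reference)
    abund <- typeAbundances(reference)
    if (length(abund) < 2L)
        stop("reference must contain at least 2 cell types")
    if (is.null(processed))
        processed <- preprocessPair(reference, query, nHvgs = nHvgs,
                                    pseudocount = pseudocount, theta = theta)
    qIds <- cellIds(query)
    labelsAll <- sort(names(abund))
    score <- matrix(0, nrow = length(qIds), ncol = length(labelsAll),
                    dimnames = list(qIds, labelsAll))
    totalWeight <- numeric(length(qIds))
    votes <- list()
    allSeries <- lapply(seq_len(nBoot), function(r)
        buildSubsetSeries(reference, seed = seed + r - 1L))
    preds <- .seriesPredictions(processed, refLabels, spec, allSeries,
                                extraRuns = .extraRuns)
    seriesPreds <- preds$series
    for (r in seq_len(nBoot)) {
        series <- allSeries[[r]]
        for (j in seq_along(series@subsets)) {
            sub <- series@subsets[[j]]
            pred <- seriesPreds[[(r - 1L) * length(series@subsets) + j]]
            assigned <- pred$label != unassignedLabel()
            w <- numeric(nrow(pred))
            if (any(assigned))
                w[assigned] <- computeWeight(abund[pred$label[assigned]],
                                             subsetCap(sub),
                                             strict = strict)
            if (any(assigned)) {
                # one vote per cell per subset, so the index pairs are unique
                ij <- cbind(match(pred$cell_id[assigned], qIds),
                            match(pred$label[assigned], labelsAll))
                score[ij] <- score[ij] + w[assigned]
            }
            totalWeight <- totalWeight + w
            votes[[length(votes) + 1L]] <- data.frame(
                cell_id = pred$cell_id, replicate = r,
                subset_cap = subsetCap(sub),
                subset_type = series@typeNames[j],
                label = pred$label, weight = unname(w),
                stringsAsFactors = FALSE)
        }
    }
    winners <- apply(score, 1L, function(s) {
        if (max(s) <= 0) unassignedLabel() else .argmaxLabel(s)
    })
    stability <- vapply(seq_along(qIds), function(i) {
        if (totalWeight[i] <= 0) 0
        else max(score[i, ]) / totalWeight[i]
    }, numeric(1))
    predictions <- data.frame(cell_id = qIds, label = unname(winners),
                              confidence = stability,
                              stringsAsFactors = FALSE)
    out <- methods::new("BootstrapResult", votes = do.call(rbind, votes),
                        scoreTable = score, predictions = predictions,
                        nBoot = nBoot)
    if (!is.null(.extraRuns))
        attr(out, "extraPredictions") <- preds$extra
    out
}

# Predictions of the classifier on every subset of a list of subset series
# (replicate-major order), plus optional extra reference column subsets
# (e.g. the full reference). For the iterative Spearman classifier all runs
# are computed in one batch sharing rank computations; other classifiers
# run subset by subset.
.seriesPredictions <- function(processed, refLabels, spec, allSeries,
                               extraRuns = NULL) {
    runCols <- unlist(lapply(allSeries, function(s)
        lapply(s@subsets, subsetIndices)), recursive = FALSE)
    nSeries <- length(runCols)
    runCols <- c(runCols, extraRuns)
    if (spec@name == "singler_like") {
        all <- .batchSinglerPredictions(processed, refLabels, spec, runCols)
    } else {
        all <- lapply(runCols, function(idx)
            predictLabels(spec, .subsetProcessed(processed$reference, idx),
                          refLabels[idx], processed$query))
    }
    list(series = all[seq_len(nSeries)],
         extra = if (length(runCols) > nSeries)
             all[(nSeries + 1L):length(runCols)] else NULL)
}

.batchSinglerPredictions <- function(processed, refLabels, spec, runCols) {
    refP <- processed$reference
    qryP <- processed$query
    labs <- refLabels
    labs[refP@zeroCells] <- NA          # zero-signal cells never vote
    if (all(is.na(labs))) stop("reference contains only zero-norm cells")
    medians <- .singlerMedians(refP@values, labs)
    live <- !qryP@zeroCells
    qIds <- colnames(qryP@values)
    res <- .singlerBatch(refP@values, labs, runCols,
                         qryP@values[, live, drop = FALSE],
                         spec@params, medians)
    lapply(res, function(r) {
        lab <- rep(unassignedLabel(), length(qIds))
        conf <- numeric(length(qIds))
        lab[live] <- r$label
        conf[live] <- pmin(pmax(r$confidence, 0), 1)
        data.frame(cell_id = qIds, label = lab, confidence = conf,
                   stringsAsFactors = FALSE)
    })
}

#' Accessors for bootstrap results
#' @param x a \linkS4class{BootstrapResult}.
#' @return \code{bootPredictions}: the aggregated prediction data.frame;
#'   \code{bootVotes}: the per-(cell, subset, replicate) vote table;
#'   \code{bootScoreTable}: the cells x labels summed-weight matrix.
#' @name bootstrap-accessors
NULL

#' @rdname bootstrap-accessors
#' @export
bootPredictions <- function(x) x@predictions

#' @rdname bootstrap-accessors
#' @export
bootVotes <- function(x) x@votes

#' @rdname bootstrap-accessors
#' @export
bootScoreTable <- function(x) x@scoreTable

#' Compare weighted bootstrapping against the plain full-reference run
#'
#' Runs both the single full-reference prediction and the weighted bootstrap
#' with identical preprocessing, scores each against the query ground truth,
#' and tabulates per-type metric differences (bootstrap minus full). Also
#' reports, per query cell, whether each path predicted it correctly.
#'
#' @inheritParams runWeightedBootstrap
#' @return List with \code{full} and \code{bootstrap}
#'   (\linkS4class{EvaluationReport}), \code{delta} (tidy data.frame:
#'   cell_type, metric, full, bootstrap, delta) and \code{perCell}
#'   (cell_id, truth, full_label, boot_label, full_correct, boot_correct).
#' @export
compareBootstrapVsFull <- function(query, reference, spec, nBoot = 20L,
                                   seed = 1L, nHvgs = 1000,
                                   pseudocount = 0.001, theta = 100,
                                   strict = FALSE) {
    truth <- .requireLabels(query)
    truthDf <- data.frame(cell_id = cellIds(query), label = truth,
                          stringsAsFactors = FALSE)
    processed <- preprocessPair(reference, query, nHvgs = nHvgs,
                                pseudocount = pseudocount, theta = theta)
    refLabels <- .requireLabels(reference)
    # the full-reference run rides along as an extra batch run so the
    # iterative Spearman classifier shares rank computations with the series
    boot <- runWeightedBootstrap(query, reference, spec, nBoot = nBoot,
                                 seed = seed, strict = strict,
                                 processed = processed,
                                 .extraRuns = list(seq_len(ncol(reference))))
    fullPred <- attr(boot, "extraPredictions")[[1L]]
    bootPred <- bootPredictions(boot)
    evFull <- evaluateLabels(fullPred, truthDf)
    evBoot <- evaluateLabels(bootPred, truthDf)
    pcF <- perClassMetrics(evFull)
    pcB <- perClassMetrics(evBoot)
    delta <- do.call(rbind, lapply(c("accuracy", "precision", "f1"),
        function(metric) data.frame(
            cell_type = pcF$cell_type, metric = metric,
            full = pcF[[metric]], bootstrap = pcB[[metric]],
            delta = pcB[[metric]] - pcF[[metric]],
            stringsAsFactors = FALSE)))
    perCell <- data.frame(
        cell_id = truthDf$cell_id, truth = truthDf$label,
        full_label = fullPred$label, boot_label = bootPred$label,
        full_correct = fullPred$label == truthDf$label,
        boot_correct = bootPred$label == truthDf$label,
        stringsAsFactors = FALSE)
    list(full = evFull, bootstrap = evBoot, delta = delta, perCell = perCell)
}
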