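# Independent brute-force oracles, deliberately written in the most direct
# per-element style so they share no code path with the implementation.

# Iterative Spearman elimination, one query cell at a time, correlations via
# stats::cor(method = "spearman").
oracleSinglerPredict <- function(refValues, refLabels, qryValues,
                                 margin = 0.05, genesPerType = 50,
                                 quantileProb = 0.8) {
    allTypes <- sort(unique(refLabels))
    med <- sapply(allTypes, function(t)
        apply(refValues[, refLabels == t, drop = FALSE], 1, median))
    rownames(med) <- rownames(refValues)
    pickGenes <- function(surv) {
        sel <- integer(0)
        for (t in surv) {
            others <- med[, setdiff(surv, t), drop = FALSE]
            sc <- med[, t] - apply(others, 1, max)
            ord <- order(-sc, rownames(med))
            sel <- c(sel, ord[seq_len(min(genesPerType, length(ord)))])
        }
        sort(unique(sel))
    }
    out <- character(ncol(qryValues))
    for (j in seq_len(ncol(qryValues))) {
        surv <- allTypes
        repeat {
            g <- pickGenes(surv)
            refIdx <- which(refLabels %in% surv)
            cors <- sapply(refIdx, function(i)
                suppressWarnings(cor(qryValues[g, j], refValues[g, i],
                                     method = "spearman")))
            cors[is.na(cors)] <- 0
            agg <- sapply(surv, function(t)
                quantile(cors[refLabels[refIdx] == t], quantileProb,
                         names = FALSE, type = 7))
            if (length(surv) == 2) {
                out[j] <- surv[order(-agg, surv)][1]
                break
            }
            lowest <- surv[order(agg, surv)][1]
            keep <- setdiff(surv[agg >= max(agg) - margin], lowest)
            if (length(keep) < 2) keep <- surv[order(-agg, surv)][1:2]
            surv <- sort(keep)
        }
    }
    out
}

# Per-class metrics from first principles (no confusion matrix machinery).
oracleMetrics <- function(pred, truth) {
    types <- sort(unique(truth))
    do.call(rbind, lapply(types, function(t) {
        tp <- sum(truth == t & pred == t)
        rec <- tp / sum(truth == t)
        prec <- if (sum(pred == t) > 0) tp / sum(pred == t) else 0
        f1 <- if (rec + prec > 0) 2 * rec * prec / (rec + prec) else 0
        data.frame(cell_type = t, accuracy = rec, precision = prec, f1 = f1,
                   stringsAsFactors = FALSE)
    }))
}

# Tukey boxplot numbers straight from sorted data.
oracleBoxplot <- function(v) {
    q1 <- quantile(v, 0.25, names = FALSE)
    q3 <- quantile(v, 0.75, names = FALSE)
    iqr <- q3 - q1
    inside <- v[v >= q1 - 1.5 * iqr & v <= q3 + 1.5 * iqr]
    list(q1 = q1, median = quantile(v, 0.5, names = FALSE), q3 = q3,
         whiskerLow = min(inside), whiskerHigh = max(inside),
         outliers = sort(v[v < q1 - 1.5 * iqr | v > q3 + 1.5 * iqr]))
}

# Reciprocal nearest neighbours by an all-pairs distance scan.
oracleMutualNn1 <- function(embedR, embedQ) {
    nR <- nrow(embedR); nQ <- nrow(embedQ)
    d <- matrix(0, nR, nQ)
    for (i in seq_len(nR)) for (j in seq_len(nQ))
        d[i, j] <- sqrt(sum((embedR[i, ] - embedQ[j, ])^2))
    pairs <- list()
    for (j in seq_len(nQ)) {
        i <- which.min(d[, j])
        if (which.min(d[i, ]) == j)
            pairs[[length(pairs) + 1]] <- c(ref = i, query = j)
    }
    pairs
}
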