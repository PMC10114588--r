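#' Score predictions against ground truth, per cell type
#'
#' Builds the confusion matrix (true types in rows; predicted types plus an
#' unassigned column) and per-type metrics. Following the field's usage for
#' label transfer benchmarks, per-type \emph{accuracy} is recall/sensitivity
#' (\eqn{TP_t / n_t}), \emph{precision} is \eqn{TP_t / \#\{pred = t\}} (0
#' for a type never predicted), and F1 is their harmonic mean (0 when both
#' vanish). Unassigned predictions count as false for their true type and
#' never enter any type's precision denominator. The macro F1 is the
#' unweighted mean of per-type F1 over true types; the micro F1 equals the
#' overall fraction of correctly labelled cells.
#'
#' @param predictions data.frame with \code{cell_id}, \code{label}.
#' @param truth data.frame with \code{cell_id}, \code{label}; the cell_id
#'   sets must match exactly.
#' @return An \linkS4class{EvaluationReport}.
#' @examples
#' pred <- data.frame(cell_id = c("c1", "c2"), label = c("A", "B"))
#' truth <- data.frame(cell_id = c("c2", "c1"), label = c("B", "A"))
#' evaluateLabels(pred, truth)  # perfect: all metrics 1
#' @export
evaluateLabels <- function(predictions, truth) {
    stopifnot(all(c("cell_id", "label") %in% names(predictions)),
              all(c("cell_id", "label") %in% names(truth)))
    if (!setequal(predictions$cell_id, truth$cell_id) ||
        anyDuplicated(predictions$cell_id) || anyDuplicated(truth$cell_id))
        stop("prediction and truth cell_id sets must match exactly")
    pred <- predictions$label[match(truth$cell_id, predictions$cell_id)]
    tru <- as.character(truth$label)
    trueTypes <- sort(unique(tru))
    predTypes <- sort(unique(c(pred, trueTypes)))
    predTypes <- c(setdiff(predTypes, unassignedLabel()),
                   if (unassignedLabel() %in% pred) unassignedLabel())
    confusion <- table(factor(tru, levels = trueTypes),
                       factor(pred, levels = predTypes))
    confusion <- matrix(as.integer(confusion), nrow = length(trueTypes),
                        dimnames = list(true = trueTypes,
                                        predicted = predTypes))
    perClass <- do.call(rbind, lapply(trueTypes, function(t) {
        tp <- sum(tru == t & pred == t)
        support <- sum(tru == t)
        nPred <- sum(pred == t)
        acc <- tp / support
        prec <- if (nPred > 0) tp / nPred else 0
        f1 <- if (acc + prec > 0) 2 * prec * acc / (prec + acc) else 0
        data.frame(cell_type = t, support = support, accuracy = acc,
                   precision = prec, f1 = f1, stringsAsFactors = FALSE)
    }))
    methods::new("EvaluationReport", confusion = confusion,
                 perClass = perClass, macroF1 = mean(perClass$f1),
                 microF1 = mean(pred == tru))
}

#' Accessors for evaluation reports
#' @param x an \linkS4class{EvaluationReport}.
#' @return \code{perClassMetrics}: the per-type metric data.frame;
#'   \code{confusionMatrix}: the integer confusion matrix; \code{macroF1},
#'   \code{microF1}: scalars.
#' @name evaluation-accessors
NULL

#' @rdname evaluation-accessors
#' @export
perClassMetrics <- function(x) x@perClass

#' @rdname evaluation-accessors
#' @export
confusionMatrix <- function(x) x@confusion

#' @rdname evaluation-accessors
#' @export
macroF1 <- function(x) x@macroF1

#' @rdname evaluation-accessors
#' @export
microF1 <- function(x) x@microF1

#' Tukey boxplot statistics of a sample
#'
#' Quartiles by linear interpolation (the standard type-7 convention;
#' configurable), whiskers at the most extreme data points still inside
#' \eqn{[Q1 - 1.5\,IQR,\; Q3 + 1.5\,IQR]}, and everything outside the
#' whiskers listed as outliers.
#'
#' @param values numeric vector with at least one finite value.
#' @param quantileType passed to \code{\link[stats]{quantile}} (default 7,
#'   linear interpolation).
#' @return List with \code{q1}, \code{median}, \code{q3}, \code{iqr},
#'   \code{whiskerLow}, \code{whiskerHigh}, \code{outliers}, \code{n}.
#' @examples
#' boxplotStats(c(1, 2, 3, 4, 100))$outliers  # 100
#' @export
boxplotStats <- function(values, quantileType = 7) {
    values <- values[is.finite(values)]
    if (length(values) == 0L) stop("need at least one finite value")
    q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE,
                  type = quantileType)
    iqr <- q[3] - q[1]
    lowFence <- q[1] - 1.5 * iqr
    highFence <- q[3] + 1.5 * iqr
    inside <- values >= lowFence & values <= highFence
    list(q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
         whiskerLow = min(values[inside]),
         whiskerHigh = max(values[inside]),
         outliers = sort(values[!inside]), n = length(values))
}

#' Confidence calibration: do correct predictions score higher?
#'
#' Per predicted cell type, splits the prediction confidences into true and
#' false groups, summarizes each as boxplot statistics, and runs a two-sided
#' Wilcoxon rank-sum test between the groups (only when both have at least
#' two members). A type is flagged significant when p < alpha. A well
#' calibrated classifier shows significantly higher confidences for its
#' correct predictions.
#'
#' @param predictions data.frame with \code{cell_id}, \code{label},
#'   \code{confidence}.
#' @param truth data.frame with \code{cell_id}, \code{label}.
#' @param alpha significance level (default 0.05).
#' @param adjust optional p-value adjustment across cell types
#'   (\code{"none"}, default, or any \code{\link[stats]{p.adjust}} method
#'   such as \code{"BH"}).
#' @return data.frame with one row per predicted type: \code{cell_type},
#'   \code{n_true}, \code{n_false}, \code{median_conf_true},
#'   \code{median_conf_false}, \code{p_value} (NA when untestable),
#'   \code{significant}; boxplot statistics for both groups are attached as
#'   the \code{"boxplots"} attribute.
#' @export
confidenceCalibration <- function(predictions, truth, alpha = 0.05,
                                  adjust = "none") {
    stopifnot("confidence" %in% names(predictions))
    if (all(is.na(predictions$confidence)))
        stop("predictions carry no confidences")
    tru <- truth$label[match(predictions$cell_id, truth$cell_id)]
    if (any(is.na(tru))) stop("every prediction needs a ground-truth row")
    correct <- predictions$label == tru
    types <- sort(unique(predictions$label))
    boxes <- list()
    rows <- lapply(types, function(t) {
        sel <- predictions$label == t & !is.na(predictions$confidence)
        confTrue <- predictions$confidence[sel & correct]
        confFalse <- predictions$confidence[sel & !correct]
        p <- NA_real_
        if (length(confTrue) >= 2L && length(confFalse) >= 2L)
            p <- suppressWarnings(
                wilcox.test(confTrue, confFalse,
                            alternative = "two.sided")$p.value)
        boxes[[t]] <<- list(
            true = if (length(confTrue)) boxplotStats(confTrue) else NULL,
            false = if (length(confFalse)) boxplotStats(confFalse) else NULL)
        data.frame(cell_type = t, n_true = length(confTrue),
                   n_false = length(confFalse),
                   median_conf_true = if (length(confTrue))
                       median(confTrue) else NA_real_,
                   median_conf_false = if (length(confFalse))
                       median(confFalse) else NA_real_,
                   p_value = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (!identical(adjust, "none"))
        out$p_value <- p.adjust(out$p_value, method = adjust)
    out$significant <- !is.na(out$p_value) & out$p_value < alpha
    attr(out, "boxplots") <- boxes
    out
}
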