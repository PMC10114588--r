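# Fixed-vote classifier stub on a 3-type imbalanced toy reference
# (A:1000, B:100, C:40): each query cell's label depends only on the
# subset's per-type cap, so the weighted aggregation can be verified against
# a hand-summed table.

stubVotes <- list(
    #       cap1000  cap100  cap40
    q1 = c("A", "A", "A"),
    q2 = c("A", "B", "C"),
    q3 = c("B", "C", "C"),
    q4 = c("C", "B", "B"),
    q5 = c("A", "C", "B"),
    q6 = c("unassigned", "unassigned", "unassigned"))

stubbedPredict <- function(spec, reference, refLabels, query) {
    cap <- max(table(refLabels))
    col <- match(cap, c(1000, 100, 40))
    lab <- vapply(colnames(processedValues(query)),
                  function(q) stubVotes[[q]][col], character(1))
    data.frame(cell_id = colnames(processedValues(query)),
               label = unname(lab), confidence = 1,
               stringsAsFactors = FALSE)
}

makeImbalancedToy <- function(seed = 1) {
    set.seed(seed)
    n <- c(A = 1000L, B = 100L, C = 40L)
    counts <- matrix(rpois(10 * sum(n), 3), nrow = 10,
                     dimnames = list(paste0("g", 1:10),
                                     paste0("r", seq_len(sum(n)))))
    ref <- ExpressionDataset(counts, labels = rep(names(n), n))
    qcounts <- matrix(rpois(10 * 6, 3), nrow = 10,
                      dimnames = list(paste0("g", 1:10), paste0("q", 1:6)))
    list(ref = ref, qry = ExpressionDataset(qcounts))
}

# Hand-summed expected score table for the stub votes above.
stubExpectedScores <- function() {
    wA <- c(1, 1 / 901, 1 / 961)
    wB <- c(1 / 901, 1, 1 / 61)
    wC <- c(1 / 961, 1 / 61, 1)
    rbind(
        q1 = c(A = sum(wA), B = 0, C = 0),
        q2 = c(A = wA[1], B = wB[2], C = wC[3]),
        q3 = c(A = 0, B = wB[1], C = wC[2] + wC[3]),
        q4 = c(A = 0, B = wB[2] + wB[3], C = wC[1]),
        q5 = c(A = wA[1], B = wB[3], C = wC[2]),
        q6 = c(A = 0, B = 0, C = 0))
}
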