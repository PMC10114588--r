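procPair <- local({
    sc <- smallScenario()
    proc <- preprocessPair(sc$ref, sc$qry, nHvgs = 200)
    list(sc = sc, proc = proc, refLabels = cellLabels(sc$ref))
})

test_that("a query cell identical to a reference cell recovers its type", {
    with(procPair, {
        refV <- processedValues(proc$reference)
        qry <- asProcessed(refV[, c(5, 200), drop = FALSE] * 1,
                           geneIds = rownames(refV),
                           cellIds = c("q1", "q2"))
        for (cls in c("centroid", "singler_like")) {
            pred <- predictLabels(classifierSpec(cls), proc$reference,
                                  refLabels, qry)
            expect_identical(pred$label, refLabels[c(5, 200)], info = cls)
        }
    })
})

test_that("a two-type reference needs no elimination loop", {
    with(procPair, {
        twoTypes <- refLabels %in% c("A", "D")
        refV <- processedValues(proc$reference)
        ref2 <- asProcessed(refV[, twoTypes] * 1)
        qv <- processedValues(proc$query)
        pred <- predictLabels(classifierSpec("singler_like"), ref2,
                              refLabels[twoTypes],
                              asProcessed(qv * 1))
        truthLab <- procPair$sc$truth$label
        sel <- truthLab %in% c("A", "D")
        expect_true(mean(pred$label[sel] == truthLab[sel]) > 0.9)
        expect_true(all(pred$label %in% c("A", "D")))
    })
})

test_that("centroid handles exact matches and symmetric ties", {
    values <- diag(4)
    rownames(values) <- paste0("g", 1:4)
    ref <- asProcessed(values, cellIds = paste0("r", 1:4))
    labs <- c("A", "A", "B", "B")
    # query equal to the A centroid
    centA <- rowMeans(values[, 1:2])
    qry <- asProcessed(cbind(q1 = centA))
    pred <- predictLabels(classifierSpec("centroid"), ref, labs, qry)
    expect_identical(pred$label, "A")
    # equidistant from both centroids: lexicographic tie-break, conf 0.5
    mid <- rowMeans(values)
    pred2 <- predictLabels(classifierSpec("centroid"), ref, labs,
                           asProcessed(cbind(q1 = mid)))
    expect_identical(pred2$label, "A")
    expect_equal(pred2$confidence, 0.5, tolerance = 1e-8)
    # single-label reference is allowed
    pred3 <- predictLabels(classifierSpec("centroid"), ref,
                           rep("A", 4), qry)
    expect_identical(pred3$label, "A")
})

test_that("iterative Spearman matches the brute-force oracle", {
    set.seed(7)
    for (i in 1:25) {
        K <- sample(2:4, 1)
        nGenes <- sample(6:20, 1)
        perType <- sample(2:7, K, replace = TRUE)
        labs <- rep(LETTERS[1:K], perType)
        refV <- matrix(rnorm(nGenes * length(labs)), nGenes)
        # planted structure so instances are not pure noise
        for (k in seq_len(K))
            refV[sample(nGenes, 2), labs == LETTERS[k]] <-
                refV[sample(nGenes, 2), labs == LETTERS[k]] + 2
        qryV <- matrix(rnorm(nGenes * 5), nGenes)
        ref <- asProcessed(refV)
        qry <- asProcessed(qryV, geneIds = rownames(refV))
        got <- predictLabels(classifierSpec("singler_like",
                                            params = list(genesPerType = 3)),
                             ref, labs, qry)
        want <- oracleSinglerPredict(processedValues(ref), labs,
                                     processedValues(qry), genesPerType = 3)
        expect_identical(got$label, want, info = paste("instance", i))
    }
})

test_that("CCA/MNN transfers labels perfectly on self-transfer", {
    with(procPair, {
        refV <- processedValues(proc$reference)
        qry <- asProcessed(refV * 1, cellIds = paste0("q", seq_len(ncol(refV))))
        pred <- predictLabels(classifierSpec("cca_mnn"), proc$reference,
                              refLabels, qry)
        expect_gt(mean(pred$label == refLabels), 0.95)
    })
})

test_that("k=1 MNN reduces to reciprocal nearest-neighbour pairs", {
    # verified against a brute-force all-pairs scan on the embedding: for
    # every query cell with a reciprocal nearest neighbour, the prediction
    # must be that neighbour's label
    sc <- smallScenario(seed = 8)
    idx <- round(seq(1, ncol(sc$ref), length.out = 40))   # spans all types
    qidx <- round(seq(1, ncol(sc$qry), length.out = 12))
    proc <- preprocessPair(sc$ref[, idx], sc$qry[, qidx], nHvgs = 60)
    labs <- cellLabels(sc$ref)[idx]
    pred <- predictLabels(classifierSpec("cca_mnn", params = list(k = 1)),
                          proc$reference, labs, proc$query)
    # recompute the embedding exactly as the classifier defines it
    std <- function(m) scLabelBoot:::.standardizeCols(m)
    X <- processedValues(proc$reference)
    Y <- processedValues(proc$query)
    cp <- crossprod(t(std(t(X))), t(std(t(Y))))
    d <- min(20, nrow(cp), ncol(cp), nrow(X))
    sv <- svd(cp, nu = d, nv = d)
    sw <- sv$d[seq_len(d)] / sv$d[1]
    l2 <- function(m) m / pmax(sqrt(rowSums(m^2)), 1e-12)
    eR <- l2(sweep(sv$u, 2, sw, "*"))
    eQ <- l2(sweep(sv$v, 2, sw, "*"))
    pairs <- oracleMutualNn1(eR, eQ)
    expect_gt(length(pairs), 0)
    for (p in pairs)
        expect_identical(pred$label[p["query"]], labs[p["ref"]])
})

test_that("top-pair forest separates planted markers and honours nRand", {
    with(procPair, {
        spec0 <- classifierSpec("toppair_forest", seed = 5)
        pred <- predictLabels(spec0, proc$reference, refLabels, proc$query)
        expect_false(any(pred$label == unassignedLabel()))  # nRand = 0
        expect_gt(mean(pred$label == procPair$sc$truth$label), 0.95)
        # constant expression degenerates to the majority class, no error
        refC <- asProcessed(matrix(1, 20, 30) + 0, cellIds = paste0("r", 1:30))
        refC@values[] <- 1 / sqrt(20)
        qc <- asProcessed(matrix(1, 20, 4) + 0, cellIds = paste0("q", 1:4))
        qc@values[] <- 1 / sqrt(20)
        predC <- predictLabels(classifierSpec("toppair_forest", seed = 1),
                               refC, rep(c("A", "B"), c(20, 10)), qc)
        expect_identical(predC$label, rep("A", 4))
    })
})

test_that("random profiles can reject queries as unassigned", {
    set.seed(9)
    refV <- rbind(matrix(rnorm(40 * 5, 5), 5), matrix(rnorm(40 * 5), 5))
    ref <- asProcessed(refV)
    labs <- rep(c("A", "B"), each = 20)
    # a shuffled-profile query should look like no reference type
    qryV <- matrix(rnorm(10 * 6, sample(c(0, 5), 60, TRUE)), 10)
    qry <- asProcessed(qryV, geneIds = rownames(refV))
    spec <- classifierSpec("toppair_forest",
                           params = list(nRand = 40), seed = 2)
    pred <- predictLabels(spec, ref, labs, qry)
    expect_true(all(pred$label %in% c("A", "B", unassignedLabel())))
})

test_that("all classifiers are invariant to reference cell order", {
    with(procPair, {
        refV <- processedValues(proc$reference)
        perm <- sample(ncol(refV))
        refPerm <- asProcessed(refV[, perm] * 1)
        for (cls in c("centroid", "singler_like", "cca_mnn",
                      "toppair_forest")) {
            spec <- classifierSpec(cls, seed = 4)
            p1 <- predictLabels(spec, proc$reference, refLabels, proc$query)
            p2 <- predictLabels(spec, refPerm, refLabels[perm], proc$query)
            expect_identical(p1$label, p2$label, info = cls)
        }
    })
})

test_that("zero-signal query cells are always unassigned", {
    with(procPair, {
        qv <- processedValues(proc$query)[, 1:3]
        qv[, 2] <- 0
        qry <- methods::new("ProcessedExpression", values = qv,
                            hvgIds = hvgIds(proc$query),
                            params = proc$query@params,
                            zeroCells = c(FALSE, TRUE, FALSE))
        for (cls in c("centroid", "singler_like", "cca_mnn",
                      "toppair_forest")) {
            pred <- predictLabels(classifierSpec(cls), proc$reference,
                                  refLabels, qry)
            expect_identical(pred$label[2], unassignedLabel(), info = cls)
            expect_identical(pred$confidence[2], 0, info = cls)
            expect_false(any(pred$label[-2] == unassignedLabel()),
                         info = cls)
        }
    })
})

test_that("classifier contracts reject invalid inputs", {
    with(procPair, {
        expect_error(predictLabels(classifierSpec("singler_like"),
                                   proc$reference, rep("A", ncol(
                                       processedValues(proc$reference))),
                                   proc$query),
                     "2 distinct labels")
        expect_error(classifierSpec("no_such_method"), "unknown classifier")
        expect_error(classifierSpec("centroid", params = list(bogus = 1)),
                     "unknown params")
    })
})
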