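test_that("generation is bit-reproducible and matches the requested design", {
    spec <- syntheticSpec(data.frame(name = c("A", "B"),
                                     abundance = c(50, 30)),
                          nGenes = 100, markersPerType = 5, seed = 7)
    b1 <- generateSynthetic(spec)
    b2 <- generateSynthetic(spec)
    a <- function(b) as.matrix(SummarizedExperiment::assay(b$dataset,
                                                           "counts"))
    expect_identical(a(b1), a(b2))
    expect_equal(unname(typeAbundances(b1$dataset)[c("A", "B")]), c(50, 30))
    counts <- a(b1)
    expect_true(all(counts >= 0) && all(counts == floor(counts)))
    # marker map genes exist and are disjoint from each other here
    expect_true(all(unlist(b1$markerMap) %in% geneIds(b1$dataset)))
    # a different cell seed redraws cells but keeps the gene model
    b3 <- generateSynthetic(spec, cellSeed = 99)
    expect_identical(b1$markerMap, b3$markerMap)
    expect_false(identical(a(b1), a(b3)))
})

test_that("marker folds are realized in the empirical means", {
    spec <- syntheticSpec(data.frame(name = c("A", "B"),
                                     abundance = c(600, 600)),
                          nGenes = 200, markersPerType = 8, markerFold = 8,
                          seed = 13)
    b <- generateSynthetic(spec)
    counts <- as.matrix(SummarizedExperiment::assay(b$dataset, "counts"))
    labs <- cellLabels(b$dataset)
    g <- b$markerMap$A[1]
    ratio <- mean(counts[g, labs == "A"]) / mean(counts[g, labs == "B"])
    expect_gt(ratio, 8 * 0.9)
    expect_lt(ratio, 8 * 1.1)
})

test_that("without markers all types are exchangeable: chance accuracy", {
    spec <- syntheticSpec(data.frame(name = c("A", "B", "C"),
                                     abundance = c(100, 100, 100)),
                          nGenes = 300, markersPerType = 5,
                          markerFold = 1, seed = 21)
    ref <- generateSynthetic(spec)$dataset
    qry <- generateSynthetic(spec, cellSeed = 77, idPrefix = "q")$dataset
    proc <- preprocessPair(ref, qry, nHvgs = 150)
    pred <- predictLabels(classifierSpec("centroid"), proc$reference,
                          cellLabels(ref), proc$query)
    acc <- mean(pred$label == cellLabels(qry))
    # 300 cells at chance 1/3: binomial 3-sigma band
    expect_lt(abs(acc - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / 300) + 0.02)
})

test_that("related pairs share markers at full fold", {
    spec <- syntheticSpec(
        data.frame(name = c("A", "B", "C"), abundance = c(50, 50, 50)),
        nGenes = 200, markersPerType = 10, markerFold = 6,
        relatedPairs = data.frame(typeA = "A", typeB = "B",
                                  sharedFraction = 0.5),
        seed = 3)
    b <- generateSynthetic(spec)
    shared <- intersect(b$markerMap$A, b$markerMap$B)
    expect_length(shared, 5L)
    expect_length(b$markerMap$B, 10L)
    expect_length(intersect(b$markerMap$A, b$markerMap$C), 0L)
})

test_that("the PBMC-like preset mirrors the published setting", {
    spec <- presetPbmcLike(seed = 5)
    expect_identical(sum(spec@cellTypes$abundance), 9148L)
    expect_identical(min(spec@cellTypes$abundance), 38L)
    expect_identical(nrow(spec@cellTypes), 9L)
    expect_identical(spec@nGenes, 2000L)
})

test_that("mosaic sources share structure but differ by batch effects", {
    specs <- presetMosaic(seed = 9, batchEffectSigma = 0.3)
    bundles <- generateSyntheticMosaic(specs, cellSeed = 4)
    # per-type pooled abundance is the sum over sources
    abs_ <- lapply(bundles, function(b) typeAbundances(b$dataset))
    pooled <- Reduce(`+`, lapply(abs_, function(a) a[names(abs_[[1]])]))
    expect_identical(min(pooled), 102L)
    # marker maps agree across sources (shared gene model)
    expect_identical(bundles[[1]]$markerMap, bundles[[2]]$markerMap)
    # per-gene means shift between sources when batch effects are on
    m1 <- Matrix::rowMeans(SummarizedExperiment::assay(
        bundles[[1]]$dataset, "counts"))
    m2 <- Matrix::rowMeans(SummarizedExperiment::assay(
        bundles[[2]]$dataset, "counts"))
    expressed <- m1 > 0.5
    relDiff <- abs(log((m1[expressed] + 0.01) / (m2[expressed] + 0.01)))
    expect_gt(median(relDiff), 0.1)
    # with sigma = 0 the sources are exchangeable up to sampling noise
    specs0 <- presetMosaic(seed = 9, batchEffectSigma = 0)
    b0 <- generateSyntheticMosaic(specs0, cellSeed = 4)
    n1 <- Matrix::rowMeans(SummarizedExperiment::assay(
        b0[[1]]$dataset, "counts"))
    n2 <- Matrix::rowMeans(SummarizedExperiment::assay(
        b0[[2]]$dataset, "counts"))
    relDiff0 <- abs(log((n1[expressed] + 0.01) / (n2[expressed] + 0.01)))
    expect_lt(median(relDiff0), median(relDiff))
})

test_that("invalid specs are rejected", {
    expect_error(syntheticSpec(data.frame(name = "A", abundance = 0)),
                 "abundances")
    expect_error(syntheticSpec(data.frame(name = c("A", "B"),
                                          abundance = c(5, 5)),
                               nGenes = 10, markersPerType = 8),
                 "nGenes")
    expect_error(syntheticSpec(data.frame(name = c("A", "B"),
                                          abundance = c(5, 5)),
                               markerFold = 0.5), "markerFold")
})
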