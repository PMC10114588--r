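test_that("perfect predictions score 1 everywhere", {
    truth <- data.frame(cell_id = paste0("c", 1:6),
                        label = rep(c("A", "B", "C"), each = 2))
    ev <- evaluateLabels(truth, truth)
    pc <- perClassMetrics(ev)
    expect_true(all(pc$accuracy == 1 & pc$precision == 1 & pc$f1 == 1))
    expect_identical(macroF1(ev), 1)
    expect_identical(microF1(ev), 1)
    expect_true(all(confusionMatrix(ev) == diag(2, 3) - 0 |
                    confusionMatrix(ev) == 0))
})

test_that("a never-predicted class scores zero, as for excluded rare types", {
    truth <- data.frame(cell_id = paste0("c", 1:6),
                        label = c("A", "A", "A", "A", "Mega", "Mega"))
    pred <- truth
    pred$label <- "A"          # the rare class is never predicted
    pc <- perClassMetrics(evaluateLabels(pred, truth))
    mega <- pc[pc$cell_type == "Mega", ]
    expect_identical(mega$accuracy, 0)
    expect_identical(mega$precision, 0)
    expect_identical(mega$f1, 0)
})

test_that("the hand-computed 2x2 confusion example checks out", {
    # confusion [[8,2],[1,9]]
    truth <- data.frame(cell_id = paste0("c", 1:20),
                        label = rep(c("X", "Y"), each = 10))
    pred <- truth
    pred$label <- c(rep("X", 8), "Y", "Y", "X", rep("Y", 9))
    pc <- perClassMetrics(evaluateLabels(pred, truth))
    x <- pc[pc$cell_type == "X", ]
    expect_equal(x$accuracy, 0.8)
    expect_equal(x$precision, 8 / 9)
    expect_equal(x$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))
})

test_that("metrics match brute-force arithmetic on random label vectors", {
    set.seed(31)
    for (i in 1:100) {
        n <- sample(5:40, 1)
        types <- LETTERS[1:sample(2:5, 1)]
        truth <- data.frame(cell_id = paste0("c", 1:n),
                            label = sample(types, n, replace = TRUE))
        pred <- truth
        pred$label <- sample(c(types, unassignedLabel()), n, replace = TRUE)
        ev <- evaluateLabels(pred, truth)
        pc <- perClassMetrics(ev)
        want <- oracleMetrics(pred$label, truth$label)
        want <- want[want$cell_type != unassignedLabel(), ]
        expect_equal(pc$accuracy, want$accuracy, info = i)
        expect_equal(pc$precision, want$precision, info = i)
        expect_equal(pc$f1, want$f1, info = i)
        # micro accuracy equals the direct fraction of correct cells
        expect_equal(microF1(ev), mean(pred$label == truth$label))
        expect_identical(sum(confusionMatrix(ev)), n)
    }
})

test_that("evaluation is invariant under consistent relabelling", {
    set.seed(5)
    truth <- data.frame(cell_id = paste0("c", 1:30),
                        label = sample(c("A", "B", "C"), 30, replace = TRUE))
    pred <- truth
    pred$label <- sample(c("A", "B", "C"), 30, replace = TRUE)
    ev1 <- evaluateLabels(pred, truth)
    swap <- c(A = "Z1", B = "Z2", C = "Z0")
    ev2 <- evaluateLabels(transform(pred, label = swap[label]),
                          transform(truth, label = swap[label]))
    expect_identical(macroF1(ev1), macroF1(ev2))
    expect_identical(microF1(ev1), microF1(ev2))
    pc1 <- perClassMetrics(ev1)
    pc2 <- perClassMetrics(ev2)
    expect_equal(sort(pc1$f1), sort(pc2$f1))
})

test_that("evaluation rejects mismatched cell id sets", {
    truth <- data.frame(cell_id = c("c1", "c2"), label = c("A", "B"))
    pred <- data.frame(cell_id = c("c1", "c3"), label = c("A", "B"))
    expect_error(evaluateLabels(pred, truth), "match exactly")
})

test_that("boxplot statistics follow the quartile and whisker rules", {
    b <- boxplotStats(c(1, 2, 3, 4, 5))
    expect_equal(b$median, 3)
    expect_equal(b$q1, 2)
    expect_equal(b$q3, 4)
    expect_length(b$outliers, 0L)
    expect_equal(b$whiskerLow, 1)
    expect_equal(b$whiskerHigh, 5)
    # constant data collapse to a point
    bc <- boxplotStats(rep(7, 10))
    expect_true(bc$q1 == 7 && bc$median == 7 && bc$q3 == 7 && bc$iqr == 0)
    expect_equal(bc$whiskerLow, bc$whiskerHigh)
    # an extreme point becomes an outlier: q3 + 1.5*iqr = 4.25 + ... < 100
    bo <- boxplotStats(c(1, 2, 3, 4, 100))
    expect_identical(bo$outliers, 100)
    expect_equal(bo$whiskerHigh, 4)
    expect_error(boxplotStats(numeric(0)), "finite value")
})

test_that("boxplot statistics match brute-force percentiles on random data", {
    set.seed(17)
    for (i in 1:50) {
        v <- rnorm(sample(3:1000, 1), sd = sample(1:5, 1))
        got <- boxplotStats(v)
        want <- oracleBoxplot(v)
        expect_equal(got$q1, want$q1)
        expect_equal(got$median, want$median)
        expect_equal(got$q3, want$q3)
        expect_equal(got$whiskerLow, want$whiskerLow)
        expect_equal(got$whiskerHigh, want$whiskerHigh)
        expect_equal(got$outliers, want$outliers)
    }
})

test_that("calibration separates informative from uninformative confidences", {
    truth <- data.frame(cell_id = paste0("c", 1:40),
                        label = rep("A", 40))
    # fully separated: correct at 0.9, wrong at 0.1, n = 20 each
    pred <- data.frame(cell_id = paste0("c", 1:40),
                       label = rep(c("A", "B"), each = 20),
                       confidence = rep(c(0.9, 0.1), each = 20))
    truth2 <- truth
    truth2$label[21:40] <- "C"   # the B predictions are all wrong
    pred$label <- "A"
    pred$confidence <- c(rep(0.9, 20), rep(0.1, 20))
    cal <- confidenceCalibration(pred, truth2)
    expect_true(cal$significant[cal$cell_type == "A"])
    expect_lt(cal$p_value[cal$cell_type == "A"], 0.05)
    # identical confidence distributions: no significance
    pred$confidence <- rep(0.5, 40)
    cal2 <- confidenceCalibration(pred, truth2)
    expect_false(any(cal2$significant))
    # all predictions correct: empty false group, still reported
    cal3 <- confidenceCalibration(
        data.frame(cell_id = truth$cell_id, label = "A",
                   confidence = runif(40)), truth)
    expect_identical(cal3$n_false, 0L)
    expect_true(is.na(cal3$p_value))
    expect_false(cal3$significant)
    expect_error(confidenceCalibration(
        data.frame(cell_id = "c1", label = "A", confidence = NA_real_),
        truth[1, ]), "no confidences")
})
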