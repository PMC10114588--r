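# Synthetic scenario builders shared across tests. Scenario parameters are
# fixed here once; tests assert on behaviour, not on tuned values.

# Small well-separated 4-type scenario for fast unit tests.
smallScenario <- function(seed = 3) {
    spec <- syntheticSpec(
        cellTypes = data.frame(name = c("A", "B", "C", "D"),
                               abundance = c(120, 90, 60, 40)),
        nGenes = 400, markersPerType = 10, markerFold = 8, seed = seed)
    ref <- generateSynthetic(spec)
    qry <- generateSynthetic(spec, cellSeed = seed + 1000,
                             abundances = c(A = 30, B = 25, C = 20, D = 15),
                             idPrefix = "q")
    list(spec = spec, ref = ref$dataset, qry = qry$dataset,
         markerMap = ref$markerMap,
         truth = data.frame(cell_id = cellIds(qry$dataset),
                            label = cellLabels(qry$dataset),
                            stringsAsFactors = FALSE))
}

# Non-overlapping scenario: 5 types, 30 markers each at fold 8, no shared
# markers -- every classifier should reach its separability ceiling here.
separableScenario <- function(seed = 11) {
    spec <- syntheticSpec(
        cellTypes = data.frame(name = c("A", "B", "C", "D", "E"),
                               abundance = c(150, 120, 90, 60, 40)),
        nGenes = 500, markersPerType = 30, markerFold = 8, seed = seed)
    ref <- generateSynthetic(spec)
    qry <- generateSynthetic(spec, cellSeed = seed + 2000,
                             abundances = c(A = 30, B = 25, C = 20,
                                            D = 15, E = 12),
                             idPrefix = "q")
    list(spec = spec, ref = ref$dataset, qry = qry$dataset,
         truth = data.frame(cell_id = cellIds(qry$dataset),
                            label = cellLabels(qry$dataset),
                            stringsAsFactors = FALSE))
}

# Size-reduced PBMC-like design: the preset's 9-type imbalance shape and
# hard rare/abundant related pair, with abundant types scaled down so
# iterative classifiers stay fast in sweeps.
smallPbmcScenario <- function(seed = 1) {
    ab <- c(600L, 450L, 300L, 200L, 140L, 100L, 70L, 60L, 38L)
    nm <- sprintf("type%02d_n%d", seq_along(ab), ab)
    syntheticSpec(
        cellTypes = data.frame(name = nm, abundance = ab),
        nGenes = 2000L, markersPerType = 20L, markerFold = 6,
        relatedPairs = data.frame(typeA = nm[3L], typeB = nm[9L],
                                  sharedFraction = 0.5),
        seed = seed)
}

# Query abundances used throughout the reference-design experiments:
# a ~5% draw per type with a floor so rare types stay measurable.
experimentQueryAbundances <- function(ab) {
    setNames(pmax(10L, as.integer(ceiling(ab / 20))), names(ab))
}

truthOf <- function(dataset) {
    data.frame(cell_id = cellIds(dataset), label = cellLabels(dataset),
               stringsAsFactors = FALSE)
}

# A tiny labelled dataset built by hand (3 cells x 4 genes).
tinyDataset <- function() {
    counts <- matrix(c(0, 2, 0, 5,
                       1, 0, 0, 0,
                       3, 0, 4, 0),
                     nrow = 4,
                     dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
    ExpressionDataset(counts, labels = c("A", "A", "B"))
}

# Build a ProcessedExpression directly from a genes x cells matrix
# (L2-normalizing the columns), bypassing the count pipeline: classifier
# tests need full control over the feature values.
asProcessed <- function(values, geneIds = NULL, cellIds = NULL) {
    if (!is.null(geneIds)) rownames(values) <- geneIds
    if (is.null(rownames(values)))
        rownames(values) <- paste0("g", seq_len(nrow(values)))
    if (!is.null(cellIds)) colnames(values) <- cellIds
    if (is.null(colnames(values)))
        colnames(values) <- paste0("c", seq_len(ncol(values)))
    nrm <- sqrt(colSums(values^2))
    zero <- nrm < 1e-12
    nrm[zero] <- 1
    values <- sweep(values, 2L, nrm, "/")
    values[, zero] <- 0
    methods::new("ProcessedExpression", values = values,
                 hvgIds = rownames(values),
                 params = list(nHvgs = nrow(values), pseudocount = 0.001,
                               theta = 100),
                 zeroCells = unname(zero))
}
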