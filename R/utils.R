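# Internal helpers shared across modules.

# Stable 31-bit hash of a string (used to derive independent per-type
# sampling substreams; must not change across sessions or platforms).
.stringHash31 <- function(x) {
    h <- 0
    for (code in utf8ToInt(x)) h <- (h * 131 + code) %% 2147483647
    as.integer(h)
}

# Derive a valid 32-bit seed from a base seed and offsets/strings.
.deriveSeed <- function(seed, ...) {
    h <- as.numeric(seed) %% 2147483647
    for (part in list(...)) {
        p <- if (is.character(part)) .stringHash31(part) else as.numeric(part)
        h <- (h * 48271 + p + 1) %% 2147483647
    }
    as.integer(h)
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    expr
}

# Average-tie ranks of every column of a matrix (equivalent to
# apply(x, 2, rank)); compiled because the iterative Spearman classifier
# re-ranks tens of thousands of cells per elimination round.
.colRanks <- function(x) {
    if (nrow(x) == 0L || ncol(x) == 0L) return(x)
    r <- .colRanksCpp(x)
    dimnames(r) <- dimnames(x)
    r
}

# Row medians over a column subset, compiled.
.rowMedians <- function(x, idx = seq_len(ncol(x))) {
    if (length(idx) == 0L) stop("empty column subset")
    .rowMediansCpp(x, as.integer(idx))
}

# Type-7 quantile of every column, compiled.
.colQuantiles <- function(x, p) .colQuantileCpp(x, p)

# Column-standardize (mean 0, unit L2 after centering) for correlation via
# crossprod. Zero-variance columns become all-zero so they contribute zero
# correlation.
.standardizeCols <- function(x) {
    r <- .colStandardizeCpp(x)
    dimnames(r) <- dimnames(x)
    r
}

# Pearson correlation between columns of a and columns of b (same nrow).
.colCor <- function(a, b) crossprod(.standardizeCols(a), .standardizeCols(b))

# Deterministic argmax over a named score vector: highest score, ties broken
# by lexicographic label order.
.argmaxLabel <- function(scores) {
    top <- names(scores)[scores >= max(scores) - 1e-12]
    sort(top)[1L]
}

.assertScalarCount <- function(x, what) {
    if (length(x) != 1L || !is.finite(x) || x < 1 || x != floor(x))
        stop(sprintf("%s must be a single integer >= 1", what), call. = FALSE)
    invisible(as.integer(x))
}
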