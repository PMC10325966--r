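# internal helpers

# run expr with a local, restorable RNG state so exported functions are
# deterministic under their seed argument without disturbing the caller's RNG
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# accept a SpatialWeights or a plain (base or Matrix) matrix
getW <- function(weights) {
    if (is(weights, "SpatialWeights")) weights@w
    else if (is.matrix(weights) || is(weights, "Matrix")) weights
    else stop("'weights' must be a SpatialWeights object or a matrix")
}

# matrix of the log-normalized expression, genes x spots
getExpr <- function(x) {
    stopifnot(is(x, "SpotExperiment"))
    if (!"logcounts" %in% SummarizedExperiment::assayNames(x))
        stop("no normalized expression found; run normalizeLog() first")
    as.matrix(SummarizedExperiment::assay(x, "logcounts"))
}

joinSubunits <- function(x) vapply(as.list(x), paste, "", collapse = "_")

# canonical key of a subunit set (order-insensitive)
subunitKey <- function(x) vapply(as.list(x), function(s)
    paste(sort(toupper(s)), collapse = "_"), "")

# shared permutation set: nPerm x n matrix of spot-index permutations
makePermSet <- function(n, nPerm, seed) {
    withSeed(seed, t(vapply(seq_len(nPerm), function(i) sample.int(n), integer(n))))
}

bhAdjust <- function(p) p.adjust(p, method = "BH")
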