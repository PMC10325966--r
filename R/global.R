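#' Per-spot composite expression of a multi-subunit complex
#'
#' Multi-subunit ligands or receptors enter the statistics as the per-spot
#' mean of their subunits' normalized expression: the arithmetic mean by
#' default, or the geometric mean for a more stringent rule (any absent
#' subunit then zeroes the complex).
#'
#' @param sample a [SpotExperiment-class] with `logcounts`.
#' @param subunits character vector of >= 1 gene symbols.
#' @param mode "arithmetic" (default) or "geometric".
#' @return numeric vector, one value per spot.
#' @export
compositeExpression <- function(sample, subunits,
                                mode = c("arithmetic", "geometric")) {
    mode <- match.arg(mode)
    subunits <- toupper(subunits)
    if (length(subunits) == 0) stop("empty subunit list")
    miss <- setdiff(subunits, toupper(rownames(sample)))
    if (length(miss))
        stop("subunit(s) not in sample: ", paste(miss, collapse = ", "))
    e <- getExpr(sample)[subunits, , drop = FALSE]
    if (mode == "arithmetic") colMeans(e)
    else apply(e, 2, function(v) prod(v)^(1 / length(v)))
}

#' Global bivariate Moran's R
#'
#' `R = sum_ij w_ij (x_i - xbar)(y_j - ybar) /
#'      (sqrt(sum (x - xbar)^2) * sqrt(sum (y - ybar)^2))`,
#' the bivariate extension of Moran's I measuring spatial association between
#' a ligand and a receptor profile. Location and positive scale changes of
#' either input leave R unchanged.
#'
#' @param x,y numeric per-spot vectors (normalized log expression).
#' @param weights a [SpatialWeights-class] or plain n x n matrix.
#' @return scalar R; `NA` if x or y is constant (the pair is then untestable).
#' @export
globalMoranR <- function(x, y, weights) {
    W <- getW(weights)
    stopifnot(length(x) == nrow(W), length(y) == nrow(W))
    xc <- x - mean(x); yc <- y - mean(y)
    dx <- sqrt(sum(xc^2)); dy <- sqrt(sum(yc^2))
    if (dx == 0 || dy == 0) return(NA_real_)
    as.numeric(sum(xc * (W %*% yc))) / (dx * dy)
}

#' Closed-form null variance of global Moran's R
#'
#' Exact variance of R under the permutation null (random re-pairing of the
#' spot labels of one variable, marginally over the other), depending only on
#' the weight matrix:
#' `Var(R) = (n^2 S2 - n (Sr + Sc) + S0^2) / (n^2 (n-1)^2)` with
#' `S2 = sum w_ij^2`, `Sr`/`Sc` the sums of squared row/column sums and `S0`
#' the total mass. For symmetric weights this coincides with the
#' row-column-sum product form; the general expression also covers directed
#' (KNN) weights. The null mean of R is exactly 0.
#'
#' @param weights a [SpatialWeights-class] or plain matrix.
#' @return scalar variance.
#' @export
analyticVarR <- function(weights) {
    W <- getW(weights)
    n <- nrow(W)
    if (n < 3) stop("need at least 3 spots")
    S0 <- sum(W)
    if (S0 == 0) stop("degenerate weight matrix (all zeros)")
    S2 <- sum(W^2)
    Sr <- sum(Matrix::rowSums(W)^2)
    Sc <- sum(Matrix::colSums(W)^2)
    (n^2 * S2 - n * (Sr + Sc) + S0^2) / (n^2 * (n - 1)^2)
}

#' One-sided z-score test for global Moran's R
#'
#' @param R observed statistic(s) (vectorized).
#' @param varR analytic null variance from [analyticVarR()].
#' @return list with `z = R / sqrt(varR)` and the one-sided upper-tail
#'   standard-normal `p`.
#' @export
zscoreTest <- function(R, varR) {
    stopifnot(all(varR > 0))
    z <- R / sqrt(varR)
    list(z = z, p = pnorm(z, lower.tail = FALSE))
}

#' Permutation test for global Moran's R
#'
#' Null draws recompute R after permuting the spot labels of the receptor
#' vector (equivalent to shuffling the weight matrix); the one-sided p-value
#' is the proportion of null draws at least as large as the observed R,
#' floored at `1 / (nPerm + 1)` so downstream log/FDR transforms stay finite.
#'
#' @param x,y per-spot vectors.
#' @param weights a [SpatialWeights-class] or matrix.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @return list with `p`, `nullDraws` (length `nPerm`) and the observed `R`.
#' @export
permutationTest <- function(x, y, weights, nPerm = 1000, seed = 1) {
    W <- getW(weights)
    n <- nrow(W)
    stopifnot(nPerm >= 1)
    R <- globalMoranR(x, y, weights)
    if (is.na(R)) return(list(p = NA_real_, nullDraws = rep(NA_real_, nPerm), R = R))
    xc <- x - mean(x); yc <- y - mean(y)
    denom <- sqrt(sum(xc^2)) * sqrt(sum(yc^2))
    a <- as.numeric(Matrix::crossprod(W, xc))   # t(W) %*% xc
    perms <- makePermSet(n, nPerm, seed)
    draws <- vapply(seq_len(nPerm),
                    function(t) sum(a * yc[perms[t, ]]) / denom, 0)
    p <- max(mean(draws >= R), 1 / (nPerm + 1))
    list(p = p, nullDraws = draws, R = R)
}

#' Fine-tuned R with univariate auto-correlation terms
#'
#' Adds weighted univariate Moran's I of the ligand (`Il`) and receptor
#' (`Ir`) to the bivariate statistic:
#' `R' = wl * Il + wr * Ir + R`. With `wl = wr = 0` this is exactly
#' [globalMoranR()]; small positive weights (e.g. `wl = 0.17`) upweight pairs
#' whose ligand field is itself spatially structured.
#'
#' @param x,y per-spot vectors.
#' @param weights a [SpatialWeights-class] or matrix.
#' @param wl,wr auto-correlation weights (defaults 0).
#' @return scalar fine-tuned statistic (`NA` on constant input).
#' @export
fineTuneR <- function(x, y, weights, wl = 0, wr = 0) {
    W <- getW(weights)
    R <- globalMoranR(x, y, weights)
    if (is.na(R)) return(NA_real_)
    moranI <- function(v) {
        vc <- v - mean(v)
        as.numeric(sum(vc * (W %*% vc))) / sum(vc^2)
    }
    wl * moranI(x) + wr * moranI(y) + R
}

#' Global screening of a ligand-receptor database
#'
#' For every database pair, builds the composite ligand and receptor vectors,
#' computes global Moran's R and a one-sided p-value by the chosen method,
#' adjusts across tested pairs by Benjamini-Hochberg, and marks pairs with
#' `fdr < fdrThreshold` as selected. Pairs whose composite ligand or receptor
#' is constant across spots are reported as untested.
#'
#' @param sample a [SpotExperiment-class] with `logcounts`.
#' @param db an [LRDatabase-class] (filtered to the sample's genes; pairs
#'   with missing subunits are dropped here with strict matching).
#' @param weights a [SpatialWeights-class].
#' @param method "zscore" (analytic null; scalable) or "permutation".
#' @param nPerm permutations for the permutation method (shared permutation
#'   set across pairs).
#' @param fdrThreshold selection threshold on adjusted values (default 0.1).
#' @param seed integer seed (permutation method).
#' @param mode composite mode passed to [compositeExpression()].
#' @return a [GlobalResult-class].
#' @export
runGlobal <- function(sample, db, weights, method = c("zscore", "permutation"),
                      nPerm = 1000, fdrThreshold = 0.1, seed = 1,
                      mode = "arithmetic") {
    method <- match.arg(method)
    db <- filterDatabase(db, sample, strict = TRUE)
    p <- db@pairs
    if (nrow(p) == 0) stop("no database pair has all subunits in the sample")
    W <- getW(weights)
    n <- nrow(W)
    stopifnot(ncol(sample) == n)
    e <- getExpr(sample)
    comp <- function(subs) {
        m <- vapply(as.list(subs), function(s) {
            if (length(s) == 1) e[s, ]
            else if (mode == "arithmetic") colMeans(e[s, , drop = FALSE])
            else apply(e[s, , drop = FALSE], 2, function(v) prod(v)^(1 / length(v)))
        }, numeric(n))
        m
    }
    X <- comp(p$ligand)      # n x P
    Y <- comp(p$receptor)
    Xc <- sweep(X, 2, colMeans(X))
    Yc <- sweep(Y, 2, colMeans(Y))
    dx <- sqrt(colSums(Xc^2)); dy <- sqrt(colSums(Yc^2))
    tested <- dx > 0 & dy > 0
    denom <- ifelse(tested, dx * dy, NA_real_)
    R <- colSums(Xc * as.matrix(W %*% Yc)) / denom
    varR <- analyticVarR(weights)
    z <- R / sqrt(varR)
    p_z <- pnorm(z, lower.tail = FALSE)
    p_perm <- rep(NA_real_, length(R))
    if (method == "permutation") {
        A <- as.matrix(Matrix::crossprod(W, Xc))
        perms <- makePermSet(n, nPerm, seed)
        exceed <- numeric(length(R))
        for (t in seq_len(nPerm)) {
            draws <- colSums(A * Yc[perms[t, ], , drop = FALSE]) / denom
            exceed <- exceed + (draws >= R)
        }
        p_perm <- pmax(exceed / nPerm, 1 / (nPerm + 1))
        p_perm[!tested] <- NA_real_
    }
    pUse <- if (method == "permutation") p_perm else p_z
    fdr <- rep(NA_real_, length(R))
    fdr[tested] <- bhAdjust(pUse[tested])
    selected <- !is.na(fdr) & fdr < fdrThreshold
    res <- S4Vectors::DataFrame(
        pair_id = p$pair_id,
        ligand = joinSubunits(p$ligand),
        receptor = joinSubunits(p$receptor),
        pathway = p$pathway,
        R = unname(R), z = unname(z), var_R = varR,
        p_perm = unname(p_perm), p_z = unname(p_z),
        fdr = unname(fdr), selected = unname(selected),
        tested = unname(tested))
    new("GlobalResult", results = res, method = method,
        nPerm = if (method == "permutation") nPerm else 0,
        seed = seed, fdrThreshold = fdrThreshold, nSpots = n)
}

#' @rdname globalResults
#' @param x a [GlobalResult-class].
#' @return the per-pair results [S4Vectors::DataFrame].
#' @export
setMethod("globalResults", "GlobalResult", function(x) x@results)

#' @rdname selectedPairs
#' @param x a [GlobalResult-class].
#' @return character vector of selected pair ids.
#' @export
setMethod("selectedPairs", "GlobalResult", function(x)
    x@results$pair_id[x@results$selected])

setMethod("show", "GlobalResult", function(object) {
    r <- object@results
    cat(sprintf("GlobalResult (%s): %d pairs over %d spots\n",
                object@method, nrow(r), object@nSpots))
    cat(sprintf("  tested: %d, selected at FDR < %g: %d\n",
                sum(r$tested), object@fdrThreshold, sum(r$selected)))
})

#' Write global results as TSV
#'
#' One row per pair with columns pair_id, ligand, receptor, pathway, R, z,
#' var_R, p_perm, p_z, fdr, selected, n_spots_tested.
#'
#' @param x a [GlobalResult-class].
#' @param path output path.
#' @export
writeGlobalResults <- function(x, path) {
    df <- as.data.frame(x@results)
    df$n_spots_tested <- x@nSpots
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}
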