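#' Cluster local interaction hits into communication patterns
#'
#' Groups selected pairs into K tissue-level patterns. Each pair's binary
#' per-spot hit vector is smoothed with a row-stochastic RBF kernel over the
#' spot coordinates (an explicit, seeded stand-in for Gaussian-process
#' expression-histology clustering), and the smoothed profiles are clustered
#' by k-means. Pattern intensity is the per-pattern mean of its members'
#' smoothed profiles.
#'
#' @param hits pairs x spots binary matrix (see [hitsMatrix()]).
#' @param coords spots x 2 matrix.
#' @param K number of patterns.
#' @param lengthScale RBF smoothing length scale (coordinate units).
#' @param seed integer seed (k-means initialization).
#' @param minHits pairs with fewer hit spots are excluded (default 10).
#' @return a [PatternResult-class] with 0-based labels.
#' @export
clusterPatterns <- function(hits, coords, K, lengthScale = 2, seed = 1,
                            minHits = 10) {
    hits <- as.matrix(hits)
    coords <- as.matrix(coords)
    stopifnot(ncol(hits) == nrow(coords))
    elig <- rowSums(hits) >= minHits
    if (sum(elig) < K)
        stop(sprintf("K = %d exceeds the %d pairs with >= %d hit spots",
                     K, sum(elig), minHits))
    hits <- hits[elig, , drop = FALSE]
    S <- as.matrix(getW(rbfWeights(coords, l = lengthScale)))
    S <- S / rowSums(S)                      # row-stochastic smoother
    prof <- hits %*% t(S)                    # pairs x spots, smoothed
    km <- withSeed(seed, kmeans(prof, centers = K, nstart = 10, iter.max = 100))
    labels <- as.integer(km$cluster - 1L)
    names(labels) <- rownames(hits)
    intensity <- t(vapply(seq_len(K) - 1L, function(k)
        colMeans(prof[labels == k, , drop = FALSE]), numeric(ncol(prof))))
    rownames(intensity) <- paste0("pattern", seq_len(K) - 1L)
    new("PatternResult", labels = labels, intensity = intensity,
        K = as.integer(K), lengthScale = lengthScale)
}

setMethod("show", "PatternResult", function(object) {
    cat(sprintf("PatternResult: %d pairs in %d patterns (length scale %g)\n",
                length(object@labels), object@K, object@lengthScale))
    print(table(pattern = object@labels))
})

#' Pathway enrichment of selected pairs
#'
#' One-sided Fisher's exact test per pathway on the 2x2 table of
#' (selected vs not) x (in pathway vs not) over all database pairs: the
#' probability that the overlap between the selected interactions and the
#' pathway's interactions arises by chance. Pathways with fewer than 2
#' selected pairs are flagged (conventionally not visualized).
#'
#' @param selectedPairs character vector of selected pair ids (subset of the
#'   database).
#' @param db the [LRDatabase-class] that was screened.
#' @return data.frame with pathway, n_selected, n_pathway, pct_of_pathway,
#'   fisher_p, flagged.
#' @export
pathwayEnrichment <- function(selectedPairs, db) {
    ids <- as.character(db@pairs$pair_id)
    pathway <- as.character(db@pairs$pathway)
    stopifnot(all(selectedPairs %in% ids))
    sel <- ids %in% selectedPairs
    pws <- unique(pathway)
    a <- b <- c_ <- d <- pv <- numeric(length(pws))
    for (i in seq_along(pws)) {
        inPw <- pathway == pws[i]
        a[i] <- sum(sel & inPw); b[i] <- sum(sel) - a[i]
        c_[i] <- sum(inPw) - a[i]; d[i] <- sum(!sel) - c_[i]
        pv[i] <- fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), 2,
                                    byrow = TRUE),
                             alternative = "greater")$p.value
    }
    res <- data.frame(pathway = pws, n_selected = a, n_pathway = a + c_,
                      pct_of_pathway = 100 * a / (a + c_), fisher_p = pv,
                      flagged = a < 2)
    res[order(res$fisher_p), ]
}

#' Cell-type edge weight for a chord diagram
#'
#' Relative edge mass sent from cell type A to cell type B for one pair:
#' `n_AB = sum_ij w_ij * senderR_i * A_i * receiverR_j * B_j`,
#' bilinear in the two cell-type weight vectors.
#'
#' @param local a [LocalResult-class] (single pair, or use `pair` to pick a
#'   column).
#' @param weights a [SpatialWeights-class] or matrix.
#' @param celltypeWeights spots x types matrix (rows ~ sum to 1).
#' @param typeA,typeB column names: sender and receiver cell types.
#' @param pair pair id or column index (default 1).
#' @return scalar edge weight.
#' @export
chordCellType <- function(local, weights, celltypeWeights, typeA, typeB,
                          pair = 1L) {
    W <- getW(weights)
    ctw <- as.matrix(celltypeWeights)
    for (tp in c(typeA, typeB))
        if (!tp %in% colnames(ctw)) stop("unknown cell type: ", tp)
    sA <- local@senderR[, pair] * ctw[, typeA]
    rB <- local@receiverR[, pair] * ctw[, typeB]
    as.numeric(sA %*% (W %*% rB))
}

#' Per-pair chord edge weights for one cell-type combination
#'
#' @param locals a multi-pair [LocalResult-class].
#' @inheritParams chordCellType
#' @return named numeric vector, one edge weight per pair.
#' @export
chordLR <- function(locals, weights, celltypeWeights, typeA, typeB) {
    ids <- colnames(locals@senderR)
    setNames(vapply(seq_along(ids), function(k)
        chordCellType(locals, weights, celltypeWeights, typeA, typeB, pair = k),
        0), ids)
}

#' Predict cell-type weights from local interaction p-values
#'
#' Ordinary least squares from the spots x pairs matrix of local p-values to
#' the spots x types cell-type weights, fitted and evaluated on all spots;
#' reports the Pearson correlation between the flattened predicted and
#' observed weight matrices. Rank-deficient predictors are solved by the
#' minimum-norm solution (pseudoinverse) with a warning.
#'
#' @param localP spots x pairs matrix (e.g. the `p` slot of a
#'   [LocalResult-class]).
#' @param celltypeWeights spots x types matrix, same spot order.
#' @return list with `coefficients`, `predicted` and `pearson`.
#' @export
celltypeRegression <- function(localP, celltypeWeights) {
    X <- cbind(intercept = 1, as.matrix(localP))
    Y <- as.matrix(celltypeWeights)
    stopifnot(nrow(X) == nrow(Y))
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
        warning("rank-deficient predictors; using the minimum-norm solution")
        sv <- svd(X)
        pos <- sv$d > max(sv$d) * 1e-10
        B <- sv$v[, pos, drop = FALSE] %*%
            ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
    } else {
        B <- qr.coef(qx, Y)
    }
    pred <- X %*% B
    list(coefficients = B, predicted = pred,
         pearson = cor(as.numeric(pred), as.numeric(Y)))
}

#' Differential interaction between conditions
#'
#' Tests, pair by pair, whether the global interaction strength (z-score)
#' differs between two sample conditions (or along a continuous covariate):
#' a Gaussian linear model of z on intercept-only (reduced) versus
#' intercept + condition (full), fitted by maximum likelihood, with
#' `lrt_stat = 2 (loglik_full - loglik_reduced)` referred to a chi-squared
#' distribution, Benjamini-Hochberg adjustment across pairs, and direction
#' labels from the z-difference quantiles among significant pairs. Missing
#' z entries (pair undetected in a sample) enter as 0.
#'
#' @param zMatrix pairs x samples numeric matrix of global z-scores (rownames
#'   = pair ids); `NA` is replaced by 0.
#' @param condition per-sample labels: a factor/character with two levels, or
#'   a numeric covariate.
#' @param fdrThreshold significance threshold (default 0.1).
#' @param quantileCut direction-label quantile (default 0.3: cutoffs at the
#'   30% and 70% quantiles of z_diff among significant pairs).
#' @return a [DifferentialResult-class].
#' @export
differentialTest <- function(zMatrix, condition, fdrThreshold = 0.1,
                             quantileCut = 0.3) {
    Z <- as.matrix(zMatrix)
    Z[is.na(Z)] <- 0
    m <- ncol(Z)
    stopifnot(length(condition) == m)
    categorical <- !is.numeric(condition)
    if (categorical) {
        condition <- factor(condition)
        if (nlevels(condition) != 2)
            stop("categorical condition must have exactly two levels")
        if (any(table(condition) == 0)) stop("a condition has zero samples")
        xnum <- as.numeric(condition == levels(condition)[1])
    } else xnum <- as.numeric(condition)
    X <- cbind(1, xnum)
    qx <- qr(X)
    lrt <- apply(Z, 1, function(z) {
        rss1 <- sum(qr.resid(qx, z)^2)
        rss0 <- sum((z - mean(z))^2)
        if (rss1 <= 0) rss1 <- .Machine$double.eps * max(1, rss0)
        max(0, m * log(rss0 / rss1))
    })
    pv <- pchisq(lrt, df = 1, lower.tail = FALSE)
    pv[lrt == 0] <- 1
    fdr <- bhAdjust(pv)
    if (categorical) {
        g1 <- condition == levels(condition)[1]
        zdiff <- rowMeans(Z[, g1, drop = FALSE]) -
            rowMeans(Z[, !g1, drop = FALSE])
    } else {
        zdiff <- apply(Z, 1, function(z) cor(z, xnum))
        zdiff[is.na(zdiff)] <- 0
    }
    label <- rep("ns", nrow(Z))
    sig <- fdr < fdrThreshold
    if (any(sig)) {
        qs <- quantile(zdiff[sig], c(quantileCut, 1 - quantileCut))
        label[sig & zdiff > qs[2]] <- "cond1_specific"
        label[sig & zdiff < qs[1]] <- "cond2_specific"
    }
    ids <- rownames(Z)
    if (is.null(ids)) ids <- paste0("pair", seq_len(nrow(Z)))
    res <- S4Vectors::DataFrame(pair_id = ids, lrt_stat = unname(lrt),
                                p = unname(pv), fdr = unname(fdr),
                                z_diff = unname(zdiff), label = label)
    zcols <- as.data.frame(Z)
    colnames(zcols) <- paste0("z_", if (is.null(colnames(Z)))
        seq_len(m) else colnames(Z))
    res <- cbind(res, S4Vectors::DataFrame(zcols))
    new("DifferentialResult", results = res, fdrThreshold = fdrThreshold,
        quantileCut = quantileCut)
}

setMethod("show", "DifferentialResult", function(object) {
    r <- object@results
    cat(sprintf("DifferentialResult: %d pairs, %d at FDR < %g\n", nrow(r),
                sum(r$fdr < object@fdrThreshold), object@fdrThreshold))
    print(table(label = r$label))
})

#' Write differential results as TSV
#'
#' @param x a [DifferentialResult-class].
#' @param path output path.
#' @export
writeDifferentialResults <- function(x, path) {
    write.table(as.data.frame(x@results), path, sep = "\t",
                row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write pattern assignments and intensity as TSV
#'
#' @param x a [PatternResult-class].
#' @param labelsPath,intensityPath output paths.
#' @export
writePatternResults <- function(x, labelsPath, intensityPath) {
    write.table(data.frame(pair_id = names(x@labels), pattern = x@labels),
                labelsPath, sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(data.frame(pattern = rownames(x@intensity), x@intensity,
                           check.names = FALSE),
                intensityPath, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(c(labelsPath, intensityPath))
}

#' Write a JSON run manifest
#'
#' @param path output path.
#' @param params named list of run parameters (seed, thresholds, ...).
#' @export
writeRunManifest <- function(path, params) {
    manifest <- c(list(package = "spaMoran",
                       version = as.character(utils::packageVersion("spaMoran")),
                       r_version = R.version.string,
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                  params)
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(path)
}
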