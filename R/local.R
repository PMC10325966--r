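#' Gene-wise standardization with clipping
#'
#' Centers and scales to unit population standard deviation (divide by n),
#' then clips values beyond `+/- clipBound` to the bound. Standardizing makes
#' local statistics comparable across pairs and samples; clipping guards the
#' heavy upper tail of sparse expression.
#'
#' @param v per-spot vector.
#' @param clipBound positive bound (default 10).
#' @return standardized, clipped vector.
#' @export
standardizeClip <- function(v, clipBound = 10) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) stop("constant vector cannot be standardized")
    pmin(pmax((v - mean(v)) / s, -clipBound), clipBound)
}

#' Local bivariate Moran's R with sender/receiver decomposition
#'
#' `R_i = R_i_sender + R_i_receiver
#'      = x'_i sum_j w_ij y'_j + y'_i sum_j w_ij x'_j`
#' on standardized inputs. The sender half attributes the signal to ligand at
#' spot i paired with receptor in its neighbourhood; the receiver half is the
#' mirror image.
#'
#' @param xs,ys standardized per-spot vectors (see [standardizeClip()]).
#' @param weights a [SpatialWeights-class] or matrix.
#' @return list with vectors `localR`, `senderR`, `receiverR`.
#' @export
localMoranR <- function(xs, ys, weights) {
    W <- getW(weights)
    stopifnot(length(xs) == nrow(W), length(ys) == nrow(W))
    senderR <- xs * as.numeric(W %*% ys)
    receiverR <- ys * as.numeric(W %*% xs)
    list(localR = senderR + receiverR, senderR = senderR, receiverR = receiverR)
}

#' Closed-form null variance of local Moran's R
#'
#' Exact per-spot variance under the permutation null (receptor spot labels
#' permuted, marginally over the ligand):
#' `Var(R_i) = s1^2 s2^2 [ 2 (n S2_i - r_i^2) / (n - 1)
#'                        + 2 (n w_ii - r_i)^2 / (n - 1)^2 ]`
#' with `S2_i = sum_j w_ij^2` and `r_i` the row sum. For large n and
#' row-normalized weights this tends to the familiar
#' `2 s1^2 s2^2 (sum_j w_ij^2 + w_ii^2)`; the exact form is what the
#' exhaustive-permutation oracle reproduces. The diagonal term drops out (to
#' order 1/n^2) in single-cell mode where `w_ii = 0`.
#'
#' @param weights a [SpatialWeights-class] or matrix.
#' @param sigma1,sigma2 population standard deviations of the two inputs
#'   (1 after [standardizeClip()]).
#' @return per-spot variance vector.
#' @export
localVariance <- function(weights, sigma1 = 1, sigma2 = 1) {
    W <- getW(weights)
    n <- nrow(W)
    stopifnot(sigma1 > 0, sigma2 > 0)
    S2i <- Matrix::rowSums(W^2)
    ri <- Matrix::rowSums(W)
    wii <- Matrix::diag(W)
    as.numeric(sigma1^2 * sigma2^2 *
        (2 * (n * S2i - ri^2) / (n - 1) + 2 * (n * wii - ri)^2 / (n - 1)^2))
}

#' Per-spot test for local interaction hits
#'
#' Computes local Moran's R for one pair, one-sided p-values by the analytic
#' z-score or by permutation (shared seeded permutation set, floored at
#' `1/(nPerm+1)`), applies the quadrant filter - a spot with below-average
#' ligand AND below-average receptor gets `p = 1`, however large its local R,
#' so that "low-low" spots never count as interactions - and thresholds
#' hits at `p < localThreshold`.
#'
#' @param xs,ys standardized per-spot vectors ([standardizeClip()]); with
#'   `standardized = FALSE` they are taken as centered-but-unscaled values and
#'   only the permutation method is available.
#' @param weights a [SpatialWeights-class] or matrix.
#' @param method "zscore" or "permutation".
#' @param nPerm,seed permutation settings.
#' @param localThreshold hit threshold on raw local p (default 0.1; no
#'   per-spot FDR is applied).
#' @param standardized set FALSE when feeding unstandardized (centered) input.
#' @return a single-pair [LocalResult-class].
#' @export
localTest <- function(xs, ys, weights, method = c("zscore", "permutation"),
                      nPerm = 1000, seed = 1, localThreshold = 0.1,
                      standardized = TRUE) {
    method <- match.arg(method)
    if (!standardized && method == "zscore")
        stop("the analytic variance assumes standardized inputs; use method = 'permutation'")
    W <- getW(weights)
    n <- nrow(W)
    lr <- localMoranR(xs, ys, weights)
    if (method == "zscore") {
        v <- localVariance(weights)
        p <- pnorm(lr$localR / sqrt(v), lower.tail = FALSE)
    } else {
        perms <- makePermSet(n, nPerm, seed)
        exceed <- numeric(n)
        for (t in seq_len(nPerm)) {
            yp <- ys[perms[t, ]]
            rp <- xs * as.numeric(W %*% yp) + yp * as.numeric(W %*% xs)
            exceed <- exceed + (rp >= lr$localR)
        }
        p <- pmax(exceed / nPerm, 1 / (nPerm + 1))
    }
    p[xs <= 0 & ys <= 0] <- 1      # quadrant suppression of low-low spots
    hits <- p < localThreshold
    asCol <- function(v) matrix(v, ncol = 1)
    new("LocalResult", localR = asCol(lr$localR), senderR = asCol(lr$senderR),
        receiverR = asCol(lr$receiverR), p = asCol(p), hits = asCol(hits),
        method = method, clipBound = NA_real_, localThreshold = localThreshold)
}

#' Local analysis of globally selected pairs
#'
#' Runs [standardizeClip()] and [localTest()] for every selected pair of a
#' global screen and collects the per-spot statistics into matrices
#' (spots x pairs). Pairs whose composite ligand or receptor is constant are
#' skipped.
#'
#' @param sample a [SpotExperiment-class].
#' @param global a [GlobalResult-class] from [runGlobal()]; alternatively a
#'   character vector of pair ids.
#' @param db the [LRDatabase-class] used for the global screen.
#' @param weights a [SpatialWeights-class].
#' @param method,nPerm,seed,localThreshold see [localTest()].
#' @param clipBound standardization clip bound (default 10).
#' @param mode composite mode.
#' @return a multi-pair [LocalResult-class]; columns named by pair id.
#' @export
runLocal <- function(sample, global, db, weights,
                     method = c("zscore", "permutation"), nPerm = 1000,
                     seed = 1, localThreshold = 0.1, clipBound = 10,
                     mode = "arithmetic") {
    method <- match.arg(method)
    ids <- if (is.character(global)) global else selectedPairs(global)
    db <- filterDatabase(db, sample, strict = TRUE)
    p <- db@pairs[db@pairs$pair_id %in% ids, ]
    if (nrow(p) == 0) stop("none of the requested pairs is present in the database")
    W <- getW(weights)
    n <- nrow(W)
    v <- localVariance(weights)
    perms <- if (method == "permutation") makePermSet(n, nPerm, seed) else NULL
    out <- lapply(seq_len(nrow(p)), function(k) {
        x <- compositeExpression(sample, as.list(p$ligand)[[k]], mode)
        y <- compositeExpression(sample, as.list(p$receptor)[[k]], mode)
        if (sd(x) == 0 || sd(y) == 0) return(NULL)
        xs <- standardizeClip(x, clipBound)
        ys <- standardizeClip(y, clipBound)
        lr <- localMoranR(xs, ys, weights)
        if (method == "zscore") {
            pv <- pnorm(lr$localR / sqrt(v), lower.tail = FALSE)
        } else {
            exceed <- numeric(n)
            for (t in seq_len(nPerm)) {
                yp <- ys[perms[t, ]]
                rp <- xs * as.numeric(W %*% yp) + yp * as.numeric(W %*% xs)
                exceed <- exceed + (rp >= lr$localR)
            }
            pv <- pmax(exceed / nPerm, 1 / (nPerm + 1))
        }
        pv[xs <= 0 & ys <= 0] <- 1
        c(lr, list(p = pv))
    })
    keep <- !vapply(out, is.null, TRUE)
    out <- out[keep]
    ids <- p$pair_id[keep]
    if (!length(out)) stop("no pair could be standardized (all constant)")
    bind <- function(f) {
        m <- vapply(out, `[[`, numeric(n), f)
        m <- matrix(m, nrow = n, dimnames = list(colnames(sample), ids))
        m
    }
    pMat <- bind("p")
    new("LocalResult", localR = bind("localR"), senderR = bind("senderR"),
        receiverR = bind("receiverR"), p = pMat,
        hits = (pMat < localThreshold) * 1, method = method,
        clipBound = clipBound, localThreshold = localThreshold)
}

#' Binary hit matrix (pairs x spots)
#'
#' @param x a [LocalResult-class].
#' @return pairs x spots 0/1 matrix, the input expected by
#'   [clusterPatterns()].
#' @rdname hitsMatrix
#' @export
setMethod("hitsMatrix", "LocalResult", function(x) t(x@hits))

setMethod("show", "LocalResult", function(object) {
    cat(sprintf("LocalResult (%s): %d spots x %d pairs\n", object@method,
                nrow(object@localR), ncol(object@localR)))
    nh <- colSums(object@hits)
    cat(sprintf("  hits per pair (p < %g): min %d, median %g, max %d\n",
                object@localThreshold, min(nh), stats::median(nh), max(nh)))
})

#' Write per-pair local tables and the hits matrix as TSV
#'
#' @param x a [LocalResult-class].
#' @param dir output directory (created if needed); one
#'   `local_<pair_id>.tsv` per pair plus `local_hits_matrix.tsv`
#'   (pairs x spots).
#' @export
writeLocalResults <- function(x, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ids <- colnames(x@localR)
    spot <- rownames(x@localR)
    if (is.null(spot)) spot <- paste0("spot", seq_len(nrow(x@localR)))
    for (k in seq_along(ids)) {
        df <- data.frame(spot_id = spot, sender_R = x@senderR[, k],
                         receiver_R = x@receiverR[, k], local_R = x@localR[, k],
                         p = x@p[, k], hit = as.logical(x@hits[, k]))
        safe <- gsub("[^A-Za-z0-9_.-]", "_", ids[k])
        write.table(df, file.path(dir, paste0("local_", safe, ".tsv")),
                    sep = "\t", row.names = FALSE, quote = FALSE)
    }
    hm <- data.frame(pair_id = ids, t(matrix(x@hits, nrow = nrow(x@hits),
                                             dimnames = list(spot, ids))),
                     check.names = FALSE)
    write.table(hm, file.path(dir, "local_hits_matrix.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    invisible(dir)
}
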