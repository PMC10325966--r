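#' RBF-kernel spatial weights
#'
#' Builds the proximity matrix `w0_ij = exp(-d_ij^2 / (2 l^2))` on Euclidean
#' spot distances, zeroes entries with kernel value below `cutoff`, optionally
#' zeroes the diagonal (single-cell resolution), and finally rescales the
#' surviving entries so the matrix sums to the number of spots
#' (`w = n / W * w0`). That order matters: the normalizing mass `W` must be
#' the mass of the matrix actually used.
#'
#' @param coords spots x 2 numeric matrix.
#' @param l positive RBF length scale, in coordinate units.
#' @param cutoff entries with unnormalized kernel value strictly below this
#'   are zeroed; in `[0, 1)`.
#' @param singleCell zero the diagonal to suppress the self-pairing term
#'   (use for single-cell-resolution platforms).
#' @return a [SpatialWeights-class].
#' @examples
#' xy <- as.matrix(expand.grid(1:5, 1:5))
#' w <- rbfWeights(xy, l = 1.2, cutoff = 0.2)
#' sum(weightsMatrix(w))  # == 25
#' @export
rbfWeights <- function(coords, l, cutoff = 0, singleCell = FALSE) {
    coords <- as.matrix(coords)
    n <- nrow(coords)
    stopifnot(n >= 2, ncol(coords) == 2, l > 0, cutoff >= 0, cutoff < 1)
    w0 <- exp(-as.matrix(dist(coords))^2 / (2 * l^2))
    w0[w0 < cutoff] <- 0
    if (singleCell) diag(w0) <- 0
    W <- sum(w0)
    if (W == 0) stop("cutoff removes all neighbours")
    w0 <- w0 * (n / W)
    new("SpatialWeights", w = packWeights(w0, n),
        params = list(kind = "rbf", l = l, cutoff = cutoff,
                      nNeighbors = NA_integer_, singleCell = singleCell))
}

#' k-nearest-neighbour spatial weights
#'
#' Binary adjacency to each spot's `nNeighbors` nearest spots (self excluded;
#' ties at the k-th distance broken by spot index order), normalized so the
#' total sum equals n. The adjacency is directed; set `symmetrize = TRUE` for
#' the symmetrized (max) version.
#'
#' @param coords spots x 2 numeric matrix.
#' @param nNeighbors number of neighbours (default 6, the contact-signalling
#'   setting for hexagonal arrays).
#' @param symmetrize make the adjacency symmetric before normalizing.
#' @return a [SpatialWeights-class] (always zero diagonal).
#' @export
knnWeights <- function(coords, nNeighbors = 6, symmetrize = FALSE) {
    coords <- as.matrix(coords)
    n <- nrow(coords)
    stopifnot(n > nNeighbors, nNeighbors >= 1)
    d <- as.matrix(dist(coords))
    w0 <- matrix(0, n, n)
    for (i in seq_len(n)) {
        o <- order(d[i, ], seq_len(n))   # deterministic tie-break by index
        o <- o[o != i][seq_len(nNeighbors)]
        w0[i, o] <- 1
    }
    if (symmetrize) w0 <- pmax(w0, t(w0))
    w0 <- w0 * (n / sum(w0))
    new("SpatialWeights", w = packWeights(w0, n),
        params = list(kind = "knn", l = NA_real_, cutoff = NA_real_,
                      nNeighbors = as.integer(nNeighbors),
                      singleCell = TRUE))
}

# dense backing for small n, sparse above; identical arithmetic contract
packWeights <- function(w0, n) {
    if (n > 5000) methods::as(methods::as(w0, "generalMatrix"), "CsparseMatrix")
    else Matrix::Matrix(w0, sparse = FALSE)
}

#' Weight matrix of a SpatialWeights object
#'
#' @param x a [SpatialWeights-class].
#' @return the underlying [Matrix::Matrix].
#' @rdname weightsMatrix
#' @export
setMethod("weightsMatrix", "SpatialWeights", function(x) x@w)

setMethod("show", "SpatialWeights", function(object) {
    p <- object@params
    n <- nrow(object@w)
    nz <- sum(object@w != 0)
    cat(sprintf("SpatialWeights (%s): %d x %d, %d nonzero (%.1f per spot)\n",
                p$kind, n, n, nz, nz / n))
    if (p$kind == "rbf")
        cat(sprintf("  l = %g, cutoff = %g, singleCell = %s\n",
                    p$l, p$cutoff, p$singleCell))
    else
        cat(sprintf("  nNeighbors = %d\n", p$nNeighbors))
})

#' Write weights as a MatrixMarket sparse file
#'
#' @param x a [SpatialWeights-class].
#' @param path output `.mtx` path.
#' @export
writeWeights <- function(x, path) {
    Matrix::writeMM(methods::as(methods::as(x@w, "generalMatrix"),
                                "CsparseMatrix"), path)
    invisible(path)
}
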