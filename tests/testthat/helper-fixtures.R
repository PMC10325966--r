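# shared fixtures built in code

# all permutations of 1..n (n small), one per row
permEnum <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- permEnum(n - 1)
    out <- matrix(0L, nrow(sub) * n, n)
    r <- 0L
    for (k in seq_len(n)) {
        blk <- cbind(k, sub + (sub >= k))
        out[r + seq_len(nrow(sub)), ] <- blk
        r <- r + nrow(sub)
    }
    out
}

randomCoords <- function(n, seed = 1) {
    set.seed(seed)
    cbind(runif(n, 0, 10), runif(n, 0, 10))
}

# a weights object with uneven, asymmetric structure for oracle tests
randomWeights <- function(n, seed = 1, symmetric = FALSE) {
    set.seed(seed)
    w0 <- matrix(runif(n * n), n)
    if (symmetric) w0 <- (w0 + t(w0)) / 2
    w0 * n / sum(w0)
}

toySample <- function(nGenes = 6, nSpots = 10, seed = 1) {
    set.seed(seed)
    cts <- matrix(rpois(nGenes * nSpots, 5), nGenes, nSpots,
                  dimnames = list(paste0("G", seq_len(nGenes)),
                                  paste0("s", seq_len(nSpots))))
    normalizeLog(SpotExperiment(cts, randomCoords(nSpots, seed)))
}

toyDb <- function() {
    LRDatabase(data.frame(
        pair_id = c("P1", "P2", "P3"),
        ligand = c("G1", "G2", "G3_G4"),
        receptor = c("G2", "G3", "G5"),
        pathway = c("A", "A", "B"),
        signalling_type = c("secreted", "secreted", "contact")))
}

# direct Eq-style double-loop evaluation used as brute-force oracle
bruteMoranR <- function(x, y, W) {
    W <- as.matrix(W)
    n <- length(x)
    num <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
        num <- num + W[i, j] * (x[i] - mean(x)) * (y[j] - mean(y))
    num / (sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2)))
}

# exhaustive-permutation variance of global R (marginal over both variables):
# for fixed standardized draws, enumerating the permutations of each side
# reproduces the exchangeable null moments exactly
exhaustiveVarGlobal <- function(W, seed = 1) {
    W <- as.matrix(W)
    n <- nrow(W)
    P <- permEnum(n)
    set.seed(seed)
    u0 <- rnorm(n); u0 <- u0 - mean(u0); u0 <- u0 / sqrt(sum(u0^2))
    v0 <- rnorm(n); v0 <- v0 - mean(v0); v0 <- v0 / sqrt(sum(v0^2))
    U <- matrix(u0[t(P)], ncol = n, byrow = TRUE)
    V <- matrix(v0[t(P)], ncol = n, byrow = TRUE)
    M <- U %*% W %*% t(V)
    mean(M^2)
}

# exhaustive-permutation per-spot variance of local R (population-sd inputs)
exhaustiveVarLocal <- function(W, seed = 1) {
    W <- as.matrix(W)
    n <- nrow(W)
    P <- permEnum(n)
    set.seed(seed)
    stdp <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
    u0 <- stdp(rnorm(n)); v0 <- stdp(rnorm(n))
    U <- matrix(u0[t(P)], ncol = n, byrow = TRUE)
    V <- matrix(v0[t(P)], ncol = n, byrow = TRUE)
    WU <- U %*% t(W); WV <- V %*% t(W)
    colMeans(U^2) * colMeans(WV^2) +
        2 * colMeans(U * WU) * colMeans(V * WV) +
        colMeans(V^2) * colMeans(WU^2)
}

# one-sided hypergeometric tail by direct summation (Fisher oracle)
hyperTail <- function(a, b, c_, d) {
    # P(X >= a) where X ~ Hypergeom(m = a+c_, n = b+d, k = a+b)
    kk <- a + b
    hi <- min(kk, a + c_)
    sum(vapply(a:hi, function(x)
        choose(a + c_, x) * choose(b + d, kk - x), 0)) /
        choose(a + b + c_ + d, kk)
}

adjustedRand <- function(a, b) {
    if (requireNamespace("mclust", quietly = TRUE))
        return(mclust::adjustedRandIndex(a, b))
    tab <- table(a, b)
    sij <- sum(choose(tab, 2))
    si <- sum(choose(rowSums(tab), 2)); sj <- sum(choose(colSums(tab), 2))
    ex <- si * sj / choose(sum(tab), 2)
    (sij - ex) / ((si + sj) / 2 - ex)
}
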