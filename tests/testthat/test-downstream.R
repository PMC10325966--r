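test_that("Fisher enrichment equals direct hypergeometric tail summation", {
    db <- LRDatabase(data.frame(
        pair_id = paste0("p", 1:100),
        ligand = paste0("L", 1:100), receptor = paste0("R", 1:100),
        pathway = rep(c("pw1", "pw2"), c(18, 82)),
        signalling_type = "secreted"))
    sel <- paste0("p", 1:10)       # 8 of pw1's first 18? construct explicitly
    sel <- paste0("p", c(1:8, 19, 20))   # 8 in pw1, 2 outside
    en <- pathwayEnrichment(sel, db)
    r1 <- en[en$pathway == "pw1", ]
    # 2x2 table: 8 selected-in, 2 selected-out, 10 unselected-in, 80 unselected-out
    expect_equal(r1$n_selected, 8)
    expect_equal(r1$fisher_p, hyperTail(8, 2, 10, 80), tolerance = 1e-12)
    expect_false(r1$flagged)

    # a pathway with no selected pairs sits at the tail (p = 1)
    en0 <- pathwayEnrichment(paste0("p", 19:28), db)
    expect_equal(en0$fisher_p[en0$pathway == "pw1"],
                 hyperTail(0, 10, 18, 72), tolerance = 1e-12)
    expect_true(en0$flagged[en0$pathway == "pw1"])

    # degenerate margin: everything selected
    enAll <- pathwayEnrichment(paste0("p", 1:100), db)
    expect_true(all(enAll$fisher_p == 1))
})

test_that("chord edge weights match the brute-force double loop and are bilinear", {
    set.seed(61)
    n <- 5
    W <- randomWeights(n, seed = 71)
    sR <- matrix(rnorm(n)); rR <- matrix(rnorm(n))
    loc <- new("LocalResult",
               localR = sR + rR, senderR = sR, receiverR = rR,
               p = matrix(runif(n)), hits = matrix(0, n, 1),
               method = "zscore", clipBound = 10, localThreshold = 0.1)
    A <- runif(n); B <- 1 - A
    ctw <- cbind(tA = A, tB = B)
    got <- chordCellType(loc, W, ctw, "tA", "tB")
    brute <- 0
    for (i in 1:n) for (j in 1:n)
        brute <- brute + W[i, j] * loc@senderR[i, 1] * A[i] *
            loc@receiverR[j, 1] * B[j]
    expect_equal(got, brute, tolerance = 1e-12)

    # single-term case: weight mass concentrated on one (sender, receiver) pair
    A1 <- c(1, 0, 0, 0, 0); B1 <- c(0, 0, 1, 0, 0)
    ctw2 <- cbind(tA = A1, tB = B1)
    expect_equal(chordCellType(loc, W, ctw2, "tA", "tB"),
                 W[1, 3] * loc@senderR[1, 1] * loc@receiverR[3, 1],
                 tolerance = 1e-12)

    # bilinearity and the rows-sum-to-1 aggregation identity
    A2 <- runif(n)
    ctw3 <- cbind(a = A, a2 = A2, b = B)
    expect_equal(chordCellType(loc, W, cbind(s = A + A2, b = B), "s", "b"),
                 chordCellType(loc, W, ctw3, "a", "b") +
                     chordCellType(loc, W, ctw3, "a2", "b"), tolerance = 1e-12)
    total <- 0
    for (ta in c("tA", "tB")) for (tb in c("tA", "tB"))
        total <- total + chordCellType(loc, W, ctw, ta, tb)
    expect_equal(total,
                 as.numeric(loc@senderR[, 1] %*% W %*% loc@receiverR[, 1]),
                 tolerance = 1e-12)

    expect_error(chordCellType(loc, W, ctw, "tA", "nope"), "unknown cell type")
})

test_that("per-pair chord weights separate pairs hitting different cell-type niches", {
    set.seed(62)
    xy <- as.matrix(expand.grid(1:10, 1:10))
    n <- nrow(xy)
    w <- rbfWeights(xy, l = 1.2, cutoff = 0.2)
    blockA <- xy[, 1] <= 4
    blockB <- xy[, 1] >= 7
    mk <- function(block) {
        x <- rnorm(n, 0, 0.2) + 2.5 * block
        standardizeClip(x)
    }
    lA <- localMoranR(mk(blockA), mk(blockA), w)
    lB <- localMoranR(mk(blockB), mk(blockB), w)
    loc <- new("LocalResult",
               localR = cbind(pA = lA$localR, pB = lB$localR),
               senderR = cbind(pA = lA$senderR, pB = lB$senderR),
               receiverR = cbind(pA = lA$receiverR, pB = lB$receiverR),
               p = matrix(0.05, n, 2), hits = matrix(1, n, 2),
               method = "zscore", clipBound = 10, localThreshold = 0.1)
    ctw <- cbind(typeA = as.numeric(blockA), typeB = as.numeric(blockB))
    eAA <- chordLR(loc, w, ctw, "typeA", "typeA")
    eBB <- chordLR(loc, w, ctw, "typeB", "typeB")
    expect_equal(unname(eAA["pA"]),
                 chordCellType(loc, w, ctw, "typeA", "typeA", pair = 1))
    # each pair's edge mass concentrates on its own niche
    expect_gt(eAA["pA"], eAA["pB"])
    expect_gt(eBB["pB"], eBB["pA"])
})

test_that("cell-type regression recovers exact linear structure and shuffles to zero", {
    set.seed(63)
    n <- 120
    P <- matrix(runif(n * 5), n)
    B <- matrix(rnorm(6 * 3), 6)
    Yexact <- cbind(1, P) %*% B
    fit <- celltypeRegression(P, Yexact)
    expect_equal(fit$pearson, 1, tolerance = 1e-8)
    # independent targets: correlation near zero
    Ynull <- matrix(rnorm(n * 3), n)
    fit0 <- celltypeRegression(P, Ynull)
    expect_lt(abs(fit0$pearson), 0.35)
    # joint spot permutation leaves the fit untouched
    perm <- sample(n)
    fitP <- celltypeRegression(P[perm, ], Yexact[perm, ])
    expect_equal(fitP$pearson, fit$pearson, tolerance = 1e-8)
    # duplicated column triggers the minimum-norm path
    expect_warning(celltypeRegression(cbind(P, P[, 1]), Yexact),
                   "rank-deficient")
})

test_that("differential LRT flags shifted pairs and respects edge cases", {
    set.seed(64)
    nPair <- 200; shifted <- 1:30
    z <- matrix(rnorm(nPair * 6), nPair,
                dimnames = list(paste0("pr", 1:nPair),
                                c("a1", "a2", "a3", "f1", "f2", "f3")))
    z[shifted, 1:3] <- z[shifted, 1:3] + 3
    cond <- c("adult", "adult", "adult", "foetus", "foetus", "foetus")
    d <- differentialTest(z, cond, fdrThreshold = 0.1)
    r <- d@results
    hitRate <- mean(r$fdr[shifted] < 0.1)
    expect_gt(hitRate, 0.7)
    # z_diff sign: adult (condition 1 by factor order) minus foetus
    expect_gt(mean(r$z_diff[shifted]), 2)
    # labels only among significant pairs, directions by quantile cuts
    expect_true(all(r$label[r$fdr >= 0.1] == "ns"))
    sig <- r$fdr < 0.1
    qs <- quantile(r$z_diff[sig], c(0.3, 0.7))
    expect_true(all(r$label[sig & r$z_diff > qs[2]] == "cond1_specific"))
    expect_true(all(r$label[sig & r$z_diff < qs[1]] == "cond2_specific"))

    # identical z across samples: zero statistic, p = 1
    z2 <- matrix(1.7, 3, 6)
    d2 <- differentialTest(z2, cond)
    expect_equal(d2@results$lrt_stat, rep(0, 3))
    expect_equal(d2@results$p, rep(1, 3))

    # NA (pair undetected in a sample) enters as z = 0
    z3 <- matrix(rnorm(12), 2, 6)
    z3na <- z3; z3na[1, 2] <- NA
    z30 <- z3; z30[1, 2] <- 0
    expect_equal(differentialTest(z3na, cond)@results$lrt_stat,
                 differentialTest(z30, cond)@results$lrt_stat)

    expect_error(differentialTest(z3, rep("adult", 6)), "two levels")
})

test_that("null LRT p-values are uniform once per-group samples are moderate", {
    set.seed(65)
    z <- matrix(rnorm(450 * 20), 450)
    d <- differentialTest(z, rep(c("a", "b"), each = 10))
    ks <- suppressWarnings(ks.test(d@results$p, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("continuous covariates run through the same LRT machinery", {
    set.seed(66)
    covar <- seq(0, 1, length.out = 12)
    z <- matrix(rnorm(100 * 12), 100)
    z[1:10, ] <- z[1:10, ] + 4 * matrix(covar, 10, 12, byrow = TRUE)
    d <- differentialTest(z, covar)
    expect_gt(mean(d@results$fdr[1:10] < 0.1), 0.7)
    expect_lt(mean(d@results$fdr[-(1:10)] < 0.1), 0.2)
})

test_that("pattern clustering groups identical profiles and recovers planted blocks", {
    set.seed(67)
    xy <- as.matrix(expand.grid(1:12, 1:12))
    n <- nrow(xy)
    blocks <- list(xy[, 1] <= 4,
                   xy[, 1] >= 9,
                   xy[, 1] > 4 & xy[, 1] < 9 & xy[, 2] <= 6)
    hits <- do.call(rbind, lapply(rep(1:3, each = 4), function(b) {
        h <- as.numeric(blocks[[b]])
        flip <- sample(which(h == 0), 2)  # sprinkle of noise
        h[flip] <- 1
        h
    }))
    rownames(hits) <- paste0("pair", 1:12)
    pat <- clusterPatterns(hits, xy, K = 3, lengthScale = 1.5, seed = 4)
    truth <- rep(1:3, each = 4)
    expect_equal(adjustedRand(pat@labels, truth), 1)
    # identical hit vectors always share a label
    hits2 <- rbind(hits, pair13 = hits[1, ])
    pat2 <- clusterPatterns(hits2, xy, K = 3, lengthScale = 1.5, seed = 4)
    expect_equal(pat2@labels[["pair13"]], pat2@labels[["pair1"]])
    # determinism under the seed
    pat3 <- clusterPatterns(hits, xy, K = 3, lengthScale = 1.5, seed = 4)
    expect_identical(pat3@labels, pat@labels)
    # smoothness: each intensity row is more autocorrelated than a permuted copy
    w <- rbfWeights(xy, l = 1.5)
    set.seed(8)
    for (k in 1:3) {
        row <- pat@intensity[k, ]
        perm <- sample(n)
        expect_gt(globalMoranR(row, row, w),
                  globalMoranR(row[perm], row[perm], w))
    }
    expect_error(clusterPatterns(hits, xy, K = 20, minHits = 10), "exceeds")
})
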