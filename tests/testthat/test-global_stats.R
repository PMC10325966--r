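test_that("composite expression reduces correctly for 1+ subunits", {
    s <- toySample()
    e <- as.matrix(SummarizedExperiment::assay(s, "logcounts"))
    expect_equal(compositeExpression(s, "G1"), e["G1", ])
    expect_equal(compositeExpression(s, c("G1", "G2")),
                 colMeans(e[c("G1", "G2"), ]))
    geo <- compositeExpression(s, c("G1", "G2"), mode = "geometric")
    expect_equal(geo, sqrt(e["G1", ] * e["G2", ]))
    # geometric mean vanishes with a zero subunit
    zeroSpot <- which(e["G1", ] == 0)
    if (length(zeroSpot)) expect_true(all(geo[zeroSpot] == 0))
    expect_error(compositeExpression(s, character(0)), "empty")
    expect_error(compositeExpression(s, "NOPE"), "NOPE")
})

test_that("global Moran's R matches the brute-force double sum", {
    set.seed(21)
    n <- 5
    W <- randomWeights(n, seed = 31)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(globalMoranR(x, y, W), bruteMoranR(x, y, W), tolerance = 1e-12)
    sw <- rbfWeights(randomCoords(n), l = 2)
    expect_equal(globalMoranR(x, y, sw),
                 bruteMoranR(x, y, as.matrix(weightsMatrix(sw))),
                 tolerance = 1e-12)
})

test_that("R is symmetric, affine-invariant, and reduces to Moran's I when x = y", {
    set.seed(22)
    n <- 12
    W <- randomWeights(n, seed = 5, symmetric = TRUE)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(globalMoranR(x, y, W), globalMoranR(y, x, W), tolerance = 1e-12)
    expect_equal(globalMoranR(2.5 * x + 3, 0.2 * y - 7, W),
                 globalMoranR(x, y, W), tolerance = 1e-12)
    # x = y: R equals the univariate auto-correlation statistic
    xc <- x - mean(x)
    moranI <- sum(xc * (W %*% xc)) / sum(xc^2)
    expect_equal(globalMoranR(x, x, W), moranI, tolerance = 1e-12)
    # empty weight support gives R = 0
    expect_equal(globalMoranR(x, y, matrix(0, n, n)), 0)
    # constant input is flagged untestable
    expect_true(is.na(globalMoranR(rep(1, n), y, W)))
})

test_that("analytic Var(R) equals the exhaustive permutation variance (n = 7)", {
    for (sym in c(FALSE, TRUE)) {
        W <- randomWeights(7, seed = 40 + sym, symmetric = sym)
        expect_equal(analyticVarR(W), exhaustiveVarGlobal(W, seed = 17),
                     tolerance = 1e-10)
    }
    sw <- rbfWeights(randomCoords(7, seed = 2), l = 3, cutoff = 0.05)
    expect_equal(analyticVarR(sw),
                 exhaustiveVarGlobal(as.matrix(weightsMatrix(sw)), seed = 3),
                 tolerance = 1e-10)
})

test_that("Var(R) is invariant to pre-normalization scaling of the kernel", {
    xy <- randomCoords(20, seed = 9)
    w1 <- rbfWeights(xy, l = 1.5)
    # scaling all coordinates and l leaves the normalized matrix unchanged,
    # so the variance depends only on the normalized structure
    w2 <- rbfWeights(xy * 10, l = 15)
    expect_equal(analyticVarR(w1), analyticVarR(w2), tolerance = 1e-12)
    expect_error(analyticVarR(matrix(0, 5, 5)), "degenerate")
})

test_that("z-score test follows the one-sided standard normal tail", {
    expect_equal(zscoreTest(0, 1)$p, 0.5)
    expect_equal(zscoreTest(1.644854 * 2, 4)$p, 0.05, tolerance = 1e-4)
    expect_gt(zscoreTest(-5, 1)$p, 0.999)
    z <- zscoreTest(c(1, 2), 4)
    expect_equal(z$z, c(0.5, 1))
})

test_that("permutation test is seeded, centred, and floored at 1/(nPerm+1)", {
    set.seed(30)
    xy <- randomCoords(40, seed = 12)
    w <- rbfWeights(xy, l = 2)
    # a strongly co-expressed pair: identical smooth field
    f <- as.numeric(weightsMatrix(w) %*% rnorm(40))
    g <- f + rnorm(40, sd = 0.01)
    pt <- permutationTest(f, g, w, nPerm = 200, seed = 7)
    expect_equal(pt$p, 1 / 201)
    pt2 <- permutationTest(f, g, w, nPerm = 200, seed = 7)
    expect_identical(pt$nullDraws, pt2$nullDraws)
    # null draws have mean 0 within Monte-Carlo error
    x <- rnorm(40); y <- rnorm(40)
    pt3 <- permutationTest(x, y, w, nPerm = 2000, seed = 8)
    expect_lt(abs(mean(pt3$nullDraws)),
              4 * sd(pt3$nullDraws) / sqrt(2000))
})

test_that("fine-tuned statistic combines auto-correlation terms as specified", {
    set.seed(33)
    n <- 15
    W <- randomWeights(n, seed = 3, symmetric = TRUE)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(fineTuneR(x, y, W, 0, 0), globalMoranR(x, y, W))
    xc <- x - mean(x)
    Il <- sum(xc * (W %*% xc)) / sum(xc^2)
    expect_equal(fineTuneR(x, y, W, 0.17, 0),
                 globalMoranR(x, y, W) + 0.17 * Il, tolerance = 1e-12)
    # x = y: I_l = I_r, result collapses to (wl + wr) I + R
    expect_equal(fineTuneR(x, x, W, 0.3, 0.2),
                 0.5 * Il + globalMoranR(x, x, W), tolerance = 1e-12)
})

test_that("runGlobal screens a database, flags degenerate pairs and applies BH", {
    sim <- simulateInteracting(simConfig(nSpots = 100, nPairs = 20,
                                         interactionFraction = 0.75, seed = 6))
    w <- rbfWeights(sim$coords, l = 1.2, cutoff = 0.2)
    # add a pair whose ligand is everywhere zero
    cts <- as.matrix(SummarizedExperiment::assay(sim$sample, "counts"))
    cts <- rbind(cts, ZLIG = 0)
    s2 <- normalizeLog(SpotExperiment(cts, sim$coords))
    dbdf <- as.data.frame(lrPairs(sim$db))[, c("pair_id", "pathway",
                                               "signalling_type")]
    dbdf$ligand <- unlist(lapply(lrPairs(sim$db)$ligand, paste, collapse = "_"))
    dbdf$receptor <- unlist(lapply(lrPairs(sim$db)$receptor, paste, collapse = "_"))
    dbdf <- rbind(dbdf, data.frame(pair_id = "ZPAIR", pathway = "PW01",
                                   signalling_type = "secreted",
                                   ligand = "ZLIG", receptor = "RC0001"))
    db2 <- LRDatabase(dbdf)
    g <- runGlobal(s2, db2, w, method = "zscore")
    r <- globalResults(g)
    zrow <- r[r$pair_id == "ZPAIR", ]
    expect_false(zrow$tested)
    expect_false(zrow$selected)
    expect_true(is.na(zrow$fdr))
    # selection is exactly fdr < threshold among tested pairs
    expect_equal(r$selected[r$tested], r$fdr[r$tested] < g@fdrThreshold)
    expect_identical(sort(selectedPairs(g)), sort(r$pair_id[r$selected]))
    # strong interaction at 75%: most pairs found
    expect_gt(sum(r$selected), 10)
    # TSV writer emits the documented columns
    path <- tempfile(fileext = ".tsv")
    writeGlobalResults(g, path)
    tab <- read.delim(path)
    expect_true(all(c("pair_id", "R", "z", "var_R", "p_z", "fdr", "selected",
                      "n_spots_tested") %in% colnames(tab)))
    expect_error(runGlobal(toySample(), LRDatabase(data.frame(
        pair_id = "q", ligand = "NOPE", receptor = "NADA", pathway = "x",
        signalling_type = "secreted")), w), "no database pair")
})

test_that("permutation and z-score p-values agree in rank on a mixed set", {
    nul <- simulateNull(simConfig(nSpots = 100, nPairs = 30, seed = 14))
    pos <- simulateInteracting(simConfig(nSpots = 100, nPairs = 30,
                                         interactionFraction = 0.5, seed = 15))
    w <- rbfWeights(nul$coords, l = 1.2, cutoff = 0.2)
    ps <- lapply(list(nul, pos), function(sm) {
        g <- runGlobal(sm$sample, sm$db, w, method = "permutation",
                       nPerm = 500, seed = 2)
        globalResults(g)[, c("p_perm", "p_z")]
    })
    p <- do.call(rbind, ps)
    expect_gt(cor(p$p_perm, p$p_z, method = "spearman"), 0.9)
})
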