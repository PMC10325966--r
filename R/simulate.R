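#' Build a simulation configuration
#'
#' Defines the study conditions for the synthetic generator. The variance
#' fractions describe the latent log-intensity ligand field; by default the
#' non-interaction variance is split 5% environment (spatial GP) / 95% white
#' noise with no intrinsic term, the noise-dominated regime typical of
#' shallow sequencing-based spatial transcriptomics, and counts are Poisson
#' with ~1 expected count per gene per spot.
#'
#' @param nSpots,grid,lengthScale,nPairs,seed see
#'   [SimulationConfig-class].
#' @param interactionFraction variance share of the spatially weighted
#'   neighbour-receptor component (paper-style levels: 0, 0.25, 0.5, 0.75,
#'   0.99).
#' @param intrinsicFraction share of the paired-receptor linear component.
#' @param envFraction share of the environmental GP; default
#'   `0.05 * (1 - interactionFraction - intrinsicFraction)`.
#' @param noiseFraction white-noise share; default fills to 1.
#' @param meanCounts,logSd Poisson depth and latent log-scale sd.
#' @param weightL,weightCutoff RBF weight parameters defining the
#'   interaction component.
#' @return a validated [SimulationConfig-class].
#' @export
simConfig <- function(nSpots = 300, grid = "lattice", lengthScale = 1.5,
                      nPairs = 100, interactionFraction = 0,
                      intrinsicFraction = 0, envFraction = NULL,
                      noiseFraction = NULL, meanCounts = 1, logSd = 0.8,
                      weightL = 1.2, weightCutoff = 0.2, seed = 1) {
    if (is.null(envFraction))
        envFraction <- 0.05 * (1 - interactionFraction - intrinsicFraction)
    if (is.null(noiseFraction))
        noiseFraction <- 1 - interactionFraction - intrinsicFraction - envFraction
    new("SimulationConfig", nSpots = nSpots, grid = grid,
        lengthScale = lengthScale, nPairs = nPairs,
        interactionFraction = interactionFraction,
        envFraction = envFraction, intrinsicFraction = intrinsicFraction,
        noiseFraction = noiseFraction, meanCounts = meanCounts, logSd = logSd,
        weightL = weightL, weightCutoff = weightCutoff, seed = seed)
}

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf("SimulationConfig: %d spots (%s), %d pairs, seed %d\n",
                object@nSpots, object@grid, object@nPairs, object@seed))
    cat(sprintf("  fractions: interaction %.3g, env %.3g, intrinsic %.3g, noise %.3g\n",
                object@interactionFraction, object@envFraction,
                object@intrinsicFraction, object@noiseFraction))
})

simCoords <- function(config) {
    n <- config@nSpots
    if (config@grid == "lattice") {
        ny <- floor(sqrt(n))
        nx <- ceiling(n / ny)
        g <- as.matrix(expand.grid(x = seq_len(nx), y = seq_len(ny)))
        g[seq_len(n), , drop = FALSE]
    } else {
        side <- sqrt(n)            # ~unit mean density, comparable to lattice
        cbind(x = runif(n, 0, side), y = runif(n, 0, side))
    }
}

# lower-triangular GP factor with a small jitter for numerical rank
gpFactor <- function(coords, l) {
    K <- exp(-as.matrix(dist(coords))^2 / (2 * l^2))
    t(chol(K + 1e-8 * diag(nrow(K))))
}

stdCols <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    s <- sqrt(colMeans(m^2))
    s[s == 0] <- 1
    sweep(m, 2, s, `/`)
}

simCounts <- function(g, meanCounts, logSd) {
    lambda <- meanCounts * exp(logSd * g - logSd^2 / 2)
    matrix(rpois(length(lambda), lambda), nrow = nrow(g))
}

simAssemble <- function(config, coords, gL, gR, components, truth) {
    P <- config@nPairs
    cl <- simCounts(gL, config@meanCounts, config@logSd)
    cr <- simCounts(gR, config@meanCounts, config@logSd)
    lg <- sprintf("LG%04d", seq_len(P))
    rc <- sprintf("RC%04d", seq_len(P))
    counts <- t(cbind(cl, cr))   # genes x spots
    rownames(counts) <- c(lg, rc)
    colnames(counts) <- sprintf("spot%04d", seq_len(config@nSpots))
    sample <- SpotExperiment(counts, coords)
    sample <- normalizeLog(sample)
    S4Vectors::metadata(sample)$components <- components
    db <- LRDatabase(data.frame(
        pair_id = paste(lg, rc, sep = "_"), ligand = lg, receptor = rc,
        pathway = sprintf("PW%02d", (seq_len(P) - 1) %% 10 + 1),
        signalling_type = "secreted"), species = "synthetic",
        version_tag = "simulated")
    list(sample = sample, db = db, truth = setNames(truth, paste(lg, rc, sep = "_")),
         coords = coords)
}

#' Simulate a zero-interaction (null) dataset
#'
#' Ligand and receptor latent fields are drawn as mutually independent
#' Gaussian processes (RBF covariance at the configured length scale) plus
#' white noise, then observed as Poisson counts. Every statistic computed on
#' these pairs is a true null.
#'
#' @param config a [SimulationConfig-class] with `interactionFraction = 0`
#'   and `intrinsicFraction = 0`.
#' @return list with `sample` (a normalized [SpotExperiment-class]), `db`
#'   (an [LRDatabase-class] registering the simulated pairs), `truth`
#'   (all `FALSE`) and `coords`. Latent component fields are stored in
#'   `metadata(sample)$components`.
#' @export
simulateNull <- function(config) {
    stopifnot(config@interactionFraction == 0, config@intrinsicFraction == 0)
    withSeed(config@seed, {
        coords <- simCoords(config)
        Lc <- gpFactor(coords, config@lengthScale)
        n <- config@nSpots; P <- config@nPairs
        fe <- config@envFraction; fn <- config@noiseFraction
        draw <- function() {
            env <- stdCols(Lc %*% matrix(rnorm(n * P), n))
            noise <- matrix(rnorm(n * P), n)
            sqrt(fe) * env + sqrt(fn) * noise
        }
        gL <- draw(); gR <- draw()
        simAssemble(config, coords, gL, gR,
                    components = list(envFraction = fe, noiseFraction = fn),
                    truth = rep(FALSE, P))
    })
}

#' Simulate spatially interacting ligand-receptor pairs
#'
#' The latent ligand field is a variance-weighted sum of four standardized
#' components: interaction (spatially weighted neighbour receptor expression,
#' `W %*% receptor` with the RBF weights of the config), environment (GP on
#' the coordinates), intrinsic (the paired receptor itself) and white noise;
#' the receptor field is an independent GP + noise mix. Pairs whose realized
#' ligand-receptor correlation is negative have the ligand sign flipped.
#'
#' @param config a [SimulationConfig-class] with `interactionFraction > 0`.
#' @param receptorField optional per-spot vector reused as the latent
#'   receptor field for every pair (e.g. a profile taken from real data).
#' @return as [simulateNull()]; `truth` is all `TRUE` and
#'   `metadata(sample)$components` holds the standardized component matrices.
#' @export
simulateInteracting <- function(config, receptorField = NULL) {
    stopifnot(config@interactionFraction > 0)
    withSeed(config@seed, {
        coords <- simCoords(config)
        Lc <- gpFactor(coords, config@lengthScale)
        n <- config@nSpots; P <- config@nPairs
        fint <- config@interactionFraction; fe <- config@envFraction
        fintr <- config@intrinsicFraction; fn <- config@noiseFraction
        # receptor: env/noise mix in the config's proportions
        eShare <- if (fe + fn > 0) fe / (fe + fn) else 0
        if (is.null(receptorField)) {
            gR <- sqrt(eShare) * stdCols(Lc %*% matrix(rnorm(n * P), n)) +
                sqrt(1 - eShare) * matrix(rnorm(n * P), n)
        } else {
            stopifnot(length(receptorField) == n)
            gR <- matrix(rep(standardizeClip(receptorField, Inf), P), n)
        }
        W <- getW(rbfWeights(coords, l = config@weightL,
                             cutoff = config@weightCutoff))
        zint <- stdCols(as.matrix(W %*% gR))
        zenv <- stdCols(Lc %*% matrix(rnorm(n * P), n))
        zintr <- stdCols(gR)
        znoise <- matrix(rnorm(n * P), n)
        gL <- sqrt(fint) * zint + sqrt(fe) * zenv + sqrt(fintr) * zintr +
            sqrt(fn) * znoise
        flip <- vapply(seq_len(P), function(k) cor(gL[, k], gR[, k]) < 0, TRUE)
        gL[, flip] <- -gL[, flip]
        simAssemble(config, coords, gL, gR,
                    components = list(interaction = zint, env = zenv,
                                      intrinsic = zintr, noise = znoise,
                                      ligand = gL, receptor = gR,
                                      flipped = flip),
                    truth = rep(TRUE, P))
    })
}

#' Maximum-likelihood variance-component fit for one ligand
#'
#' Fits a zero-mean multivariate-normal model to the standardized ligand
#' profile whose covariance is a weighted sum of four kernels: a linear
#' kernel on the receptor subunit expression (intrinsic), an RBF kernel on
#' the coordinates (environment), the covariance of the spatially weighted
#' receptor profile (interaction), and the identity (noise). Kernels are
#' trace-normalized so the fitted weights are directly comparable variance
#' fractions.
#'
#' @param sample a normalized [SpotExperiment-class].
#' @param ligand,receptor gene symbols (receptor may list several subunits).
#' @param weights a [SpatialWeights-class] defining the interaction kernel.
#' @param lengthScale RBF length scale of the environmental kernel.
#' @param nStarts number of seeded optimizer restarts (default 3).
#' @param seed integer seed.
#' @return list with `fractions` (named, summing to 1), `variances` (raw
#'   component weights), `negloglik`, `convergence` and `gradNorm`.
#' @export
fitVarianceComponents <- function(sample, ligand, receptor, weights,
                                  lengthScale = 1.5, nStarts = 3, seed = 1) {
    y <- standardizeClip(compositeExpression(sample, ligand), Inf)
    n <- length(y)
    Yr <- t(getExpr(sample)[toupper(receptor), , drop = FALSE])
    Yr <- stdCols(Yr)
    W <- as.matrix(getW(weights))
    coords <- spatialCoords(sample)
    tnorm <- function(K) {
        tk <- sum(diag(K))
        if (tk < 1e-12) diag(n) else K * (n / tk)
    }
    WY <- W %*% Yr
    Ks <- list(
        intrinsic = tnorm(Yr %*% t(Yr) / ncol(Yr)),
        environment = tnorm(exp(-as.matrix(dist(coords))^2 / (2 * lengthScale^2))),
        interaction = tnorm(WY %*% t(WY) / ncol(WY)),
        noise = diag(n))
    nll <- function(logs) {
        s <- exp(logs)
        Sig <- s[1] * Ks[[1]] + s[2] * Ks[[2]] + s[3] * Ks[[3]] + s[4] * diag(n)
        ch <- tryCatch(chol(Sig), error = function(e) NULL)
        if (is.null(ch)) {
            ch <- tryCatch(chol(Sig + 1e-6 * diag(n)),
                           error = function(e) NULL)
            if (is.null(ch)) return(1e10)
        }
        a <- backsolve(ch, forwardsolve(t(ch), y))
        sum(log(diag(ch))) + 0.5 * sum(y * a) + 0.5 * n * log(2 * pi)
    }
    fits <- withSeed(seed, lapply(seq_len(nStarts), function(i) {
        init <- log(pmax(runif(4, 0.05, 1), 1e-3))
        optim(init, nll, method = "L-BFGS-B", lower = -12, upper = 5,
              control = list(factr = 1e7, maxit = 200))
    }))
    best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
    s <- exp(best$par)
    eps <- 1e-5
    g <- vapply(seq_len(4), function(i) {
        d <- best$par; d[i] <- d[i] + eps
        (nll(d) - best$value) / eps
    }, 0)
    if (best$convergence != 0)
        warning("optimizer did not report convergence; |grad| = ",
                signif(sqrt(sum(g^2)), 3))
    list(fractions = setNames(s / sum(s), names(Ks)),
         variances = setNames(s, names(Ks)),
         negloglik = best$value, convergence = best$convergence,
         gradNorm = sqrt(sum(g^2)))
}
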