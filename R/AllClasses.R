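#' @import methods
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importClassesFrom Matrix Matrix
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom stats cor dist fisher.test kmeans p.adjust pchisq pnorm quantile
#'   rnorm rpois runif sd optim setNames
#' @importFrom utils read.csv read.delim write.table
NULL

#' SpotExperiment: expression and coordinates for one spatial slide
#'
#' Extends [SingleCellExperiment::SingleCellExperiment] (genes x spots).
#' The `counts` assay holds raw counts; `logcounts` is filled by
#' [normalizeLog()]. Planar spot coordinates (platform units) live in
#' `colData` columns `coord_x` / `coord_y` and are returned as a matrix by
#' [spatialCoords()].
#'
#' Gene names are uppercased on construction so that matching against a
#' ligand-receptor database is case-insensitive, and must be unique.
#'
#' @aliases SpotExperiment-class
#' @export
setClass("SpotExperiment", contains = "SingleCellExperiment")

setValidity("SpotExperiment", function(object) {
    msg <- NULL
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("coord_x", "coord_y") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'coord_x' and 'coord_y'")
    else if (anyNA(cd$coord_x) || anyNA(cd$coord_y))
        msg <- c(msg, "spot coordinates must not contain NA")
    rn <- rownames(object)
    if (is.null(rn) || anyDuplicated(toupper(rn)))
        msg <- c(msg, "gene names must be present and unique after uppercasing")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "spot ids must be present and unique")
    if ("counts" %in% SummarizedExperiment::assayNames(object)) {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (min(cts) < 0) msg <- c(msg, "raw counts must be non-negative")
    }
    if ("logcounts" %in% SummarizedExperiment::assayNames(object)) {
        lc <- SummarizedExperiment::assay(object, "logcounts")
        if (any(!is.finite(as.matrix(lc))))
            msg <- c(msg, "normalized expression must be finite")
    }
    if (is.null(msg)) TRUE else msg
})

#' SpatialWeights: normalized spatial proximity matrix
#'
#' Holds the n x n non-negative weight matrix used by all Moran statistics,
#' together with its construction parameters. After construction the total
#' mass of the matrix equals the number of spots (sum(w) == n), which is the
#' element-wise normalization the statistics assume.
#'
#' @slot w a [Matrix::Matrix] (dense or sparse), non-negative, sum == n.
#' @slot params list with elements `kind` ("rbf" or "knn"), `l`, `cutoff`,
#'   `nNeighbors`, `singleCell`.
#' @aliases SpatialWeights-class
#' @export
setClass("SpatialWeights",
    representation(w = "Matrix", params = "list"))

setValidity("SpatialWeights", function(object) {
    msg <- NULL
    w <- object@w
    n <- nrow(w)
    if (n != ncol(w)) msg <- c(msg, "weight matrix must be square")
    if (any(is.na(w@x)) || (length(w@x) && min(w@x) < 0))
        msg <- c(msg, "weights must be non-negative and free of NA")
    s <- sum(w)
    if (n >= 2 && abs(s - n) > 1e-8 * n)
        msg <- c(msg, sprintf("weights must sum to n (= %d); got %.8g", n, s))
    if (isTRUE(object@params$singleCell) && any(Matrix::diag(w) != 0))
        msg <- c(msg, "single-cell weights must have a zero diagonal")
    if (is.null(msg)) TRUE else msg
})

#' LRDatabase: curated ligand-receptor pair records
#'
#' @slot pairs a [S4Vectors::DataFrame] with columns `pair_id` (character,
#'   unique), `ligand` and `receptor` ([S4Vectors::CharacterList] of gene
#'   symbols, >= 1 subunit each), `pathway` (character) and
#'   `signalling_type` (one of "secreted", "ecm", "contact").
#' @slot species character scalar.
#' @slot version_tag character scalar.
#' @aliases LRDatabase-class
#' @export
setClass("LRDatabase",
    representation(pairs = "DataFrame", species = "character",
                   version_tag = "character"))

setValidity("LRDatabase", function(object) {
    msg <- NULL
    p <- object@pairs
    need <- c("pair_id", "ligand", "receptor", "pathway", "signalling_type")
    if (!all(need %in% colnames(p)))
        msg <- c(msg, paste("pairs must have columns:", paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(p$pair_id)) msg <- c(msg, "pair_id must be unique")
        if (nrow(p) && (any(lengths(p$ligand) < 1) || any(lengths(p$receptor) < 1)))
            msg <- c(msg, "every pair needs at least one ligand and one receptor subunit")
        bad <- setdiff(unique(p$signalling_type), c("secreted", "ecm", "contact"))
        if (length(bad))
            msg <- c(msg, paste("unknown signalling_type:", paste(bad, collapse = ", ")))
    }
    if (is.null(msg)) TRUE else msg
})

#' GlobalResult: per-pair global Moran's R statistics
#'
#' @slot results [S4Vectors::DataFrame], one row per pair: `pair_id`,
#'   `ligand`, `receptor`, `pathway`, `R`, `z`, `var_R`, `p_perm`, `p_z`,
#'   `fdr`, `selected`, `tested`.
#' @slot method "permutation" or "zscore".
#' @slot nPerm number of permutations used (0 for pure z-score runs).
#' @slot seed integer seed of the run.
#' @slot fdrThreshold selection threshold on BH-adjusted values.
#' @slot nSpots number of spots tested.
#' @aliases GlobalResult-class
#' @export
setClass("GlobalResult",
    representation(results = "DataFrame", method = "character",
                   nPerm = "numeric", seed = "numeric",
                   fdrThreshold = "numeric", nSpots = "numeric"))

#' LocalResult: per-spot local Moran's R statistics for one or more pairs
#'
#' All matrix slots are spots x pairs; single-pair results are one-column
#' matrices. `localR` equals `senderR + receiverR` elementwise, and `hits`
#' marks spots with `p < localThreshold` that survive the quadrant filter.
#'
#' @aliases LocalResult-class
#' @export
setClass("LocalResult",
    representation(localR = "matrix", senderR = "matrix",
                   receiverR = "matrix", p = "matrix", hits = "matrix",
                   method = "character", clipBound = "numeric",
                   localThreshold = "numeric"))

setValidity("LocalResult", function(object) {
    msg <- NULL
    d <- dim(object@localR)
    for (s in c("senderR", "receiverR", "p", "hits"))
        if (!identical(dim(slot(object, s)), d))
            msg <- c(msg, paste("slot", s, "must match dim of localR"))
    if (max(abs(object@localR - (object@senderR + object@receiverR))) > 1e-8)
        msg <- c(msg, "localR must equal senderR + receiverR")
    if (length(object@p) && (min(object@p) < 0 || max(object@p) > 1))
        msg <- c(msg, "p must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' PatternResult: communication patterns of local interaction hits
#'
#' @slot labels named integer vector, one 0-based pattern label per pair.
#' @slot intensity K x spots non-negative matrix of per-pattern mean
#'   smoothed hit intensity.
#' @slot K number of patterns.
#' @slot lengthScale RBF length scale used to smooth hit profiles.
#' @aliases PatternResult-class
#' @export
setClass("PatternResult",
    representation(labels = "integer", intensity = "matrix",
                   K = "integer", lengthScale = "numeric"))

#' DifferentialResult: cross-sample differential interaction test
#'
#' @slot results [S4Vectors::DataFrame], one row per pair: `pair_id`,
#'   `lrt_stat`, `p`, `fdr`, `z_diff`, `label`, plus one `z_<sample>` column
#'   per sample.
#' @slot fdrThreshold,quantileCut thresholds used for the direction labels.
#' @aliases DifferentialResult-class
#' @export
setClass("DifferentialResult",
    representation(results = "DataFrame", fdrThreshold = "numeric",
                   quantileCut = "numeric"))

#' SimulationConfig: study conditions for the synthetic-data generator
#'
#' Variance fractions refer to the latent (log-intensity) ligand field and
#' must sum to 1; counts are then drawn as Poisson with a log-normal
#' intensity, emulating shallow sequencing-based spatial transcriptomics.
#'
#' @slot nSpots number of spots.
#' @slot grid "lattice" (near-square unit grid) or "random" (uniform square).
#' @slot lengthScale RBF length scale of the latent Gaussian-process fields,
#'   in grid units.
#' @slot nPairs number of simulated ligand-receptor pairs.
#' @slot interactionFraction variance share of the spatially-weighted
#'   neighbour-receptor component (0 to 0.99).
#' @slot envFraction,intrinsicFraction,noiseFraction remaining shares
#'   (environment GP, paired-receptor linear term, white noise).
#' @slot meanCounts expected counts per gene per spot (sequencing depth).
#' @slot logSd standard deviation of the latent field on the log scale.
#' @slot weightL,weightCutoff RBF parameters of the weight matrix that
#'   defines the interaction component (W %*% receptor).
#' @slot seed integer seed.
#' @aliases SimulationConfig-class
#' @export
setClass("SimulationConfig",
    representation(nSpots = "numeric", grid = "character",
                   lengthScale = "numeric", nPairs = "numeric",
                   interactionFraction = "numeric", envFraction = "numeric",
                   intrinsicFraction = "numeric", noiseFraction = "numeric",
                   meanCounts = "numeric", logSd = "numeric",
                   weightL = "numeric", weightCutoff = "numeric",
                   seed = "numeric"))

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    tot <- object@interactionFraction + object@envFraction +
        object@intrinsicFraction + object@noiseFraction
    if (abs(tot - 1) > 1e-8)
        msg <- c(msg, sprintf("variance fractions must sum to 1 (got %.10g)", tot))
    if (object@interactionFraction < 0 || object@interactionFraction > 0.99)
        msg <- c(msg, "interactionFraction must lie in [0, 0.99]")
    if (min(object@envFraction, object@intrinsicFraction, object@noiseFraction) < 0)
        msg <- c(msg, "variance fractions must be non-negative")
    if (!object@grid %in% c("lattice", "random"))
        msg <- c(msg, "grid must be 'lattice' or 'random'")
    if (object@nSpots < 4) msg <- c(msg, "nSpots must be >= 4")
    if (object@lengthScale <= 0) msg <- c(msg, "lengthScale must be positive")
    if (is.null(msg)) TRUE else msg
})
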