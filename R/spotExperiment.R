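#' Construct a SpotExperiment from counts and coordinates
#'
#' @param counts genes x spots matrix of raw counts (rownames = gene symbols,
#'   colnames = spot ids). Gene symbols are uppercased; duplicated symbols are
#'   collapsed by summing their counts (with a warning).
#' @param coords spots x 2 numeric matrix of planar coordinates, rows matching
#'   the columns of `counts`.
#' @return a [SpotExperiment-class] with a `counts` assay. Call
#'   [normalizeLog()] to fill `logcounts` before computing statistics.
#' @examples
#' cts <- matrix(rpois(20, 3), 4, 5,
#'               dimnames = list(paste0("G", 1:4), paste0("s", 1:5)))
#' xy <- cbind(1:5, 1)
#' spe <- SpotExperiment(cts, xy)
#' @export
SpotExperiment <- function(counts, coords) {
    counts <- as.matrix(counts)
    coords <- as.matrix(coords)
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("spot", seq_len(ncol(counts)))
    if (nrow(coords) != ncol(counts))
        stop(sprintf(
            "dimension mismatch: counts has %d spots but coords has %d rows",
            ncol(counts), nrow(coords)))
    if (ncol(coords) != 2) stop("coords must have exactly two columns (x, y)")
    if (is.null(rownames(counts)))
        stop("counts must have gene symbols as rownames")
    rownames(counts) <- toupper(rownames(counts))
    if (anyDuplicated(rownames(counts))) {
        warning("duplicate gene symbols collapsed by summing counts")
        counts <- rowsum(counts, rownames(counts))
    }
    if (min(counts) < 0) stop("raw counts must be non-negative")
    cd <- S4Vectors::DataFrame(coord_x = as.numeric(coords[, 1]),
                               coord_y = as.numeric(coords[, 2]),
                               row.names = colnames(counts))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts), colData = cd)
    new("SpotExperiment", sce)
}

#' Spot coordinates
#'
#' @param x a [SpotExperiment-class].
#' @return spots x 2 numeric matrix (columns x, y; rownames = spot ids).
#' @export
setMethod("spatialCoords", "SpotExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    m <- cbind(x = cd$coord_x, y = cd$coord_y)
    rownames(m) <- colnames(x)
    m
})

#' Library-size normalization and log transform
#'
#' Fills the `logcounts` assay with `log(1 + scale * count / spot_total)`,
#' where `spot_total` is the spot's total count over all genes. Spots with a
#' zero total get an all-zero expression column (with a warning).
#'
#' @param x a [SpotExperiment-class] with a `counts` assay.
#' @param scale positive target library size (default 1e4).
#' @return the object with `logcounts` filled.
#' @rdname normalizeLog
#' @export
setMethod("normalizeLog", "SpotExperiment", function(x, scale = 1e4) {
    stopifnot(is.numeric(scale), scale > 0)
    cts <- as.matrix(SummarizedExperiment::assay(x, "counts"))
    tot <- colSums(cts)
    if (any(tot == 0)) {
        warning(sum(tot == 0), " spot(s) with zero total count; expression set to 0")
    }
    sf <- ifelse(tot > 0, scale / tot, 0)
    SummarizedExperiment::assay(x, "logcounts") <-
        log1p(sweep(cts, 2, sf, `*`))
    validObject(x)
    x
})

setMethod("show", "SpotExperiment", function(object) {
    cat(sprintf("SpotExperiment: %d genes x %d spots\n",
                nrow(object), ncol(object)))
    cat("assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
    xy <- spatialCoords(object)
    cat(sprintf("coordinate range: x [%g, %g], y [%g, %g]\n",
                min(xy[, 1]), max(xy[, 1]), min(xy[, 2]), max(xy[, 2])))
})

#' Read a spatial sample from disk
#'
#' Supports two layouts: a dense CSV/TSV of counts (spots x genes, first
#' column = spot id) or a 10x-style MatrixMarket triplet (`matrix.mtx` +
#' `barcodes.tsv` + `features.tsv`, genes x spots). Coordinates are a CSV/TSV
#' with either (spot id, x, y) - matched to counts by id - or two plain
#' numeric columns taken in file order.
#'
#' @param countsPath path to the counts CSV/TSV, or to the directory (or
#'   `.mtx` file) of an MTX triplet.
#' @param coordsPath path to the coordinates CSV/TSV.
#' @param format "csv" or "mtx".
#' @return a [SpotExperiment-class] with raw counts; `logcounts` is left
#'   empty until [normalizeLog()] is called.
#' @export
readSpotSample <- function(countsPath, coordsPath, format = c("csv", "mtx")) {
    format <- match.arg(format)
    if (format == "csv") {
        tab <- readDelimAuto(countsPath)
        spotIds <- as.character(tab[[1]])
        counts <- t(as.matrix(tab[, -1, drop = FALSE]))
        colnames(counts) <- spotIds
    } else {
        dir <- countsPath
        if (grepl("\\.mtx$", countsPath)) dir <- dirname(countsPath)
        mtx <- file.path(dir, "matrix.mtx")
        if (!file.exists(mtx) && grepl("\\.mtx$", countsPath)) mtx <- countsPath
        counts <- as.matrix(Matrix::readMM(mtx))
        bc <- read.delim(file.path(dir, "barcodes.tsv"), header = FALSE)
        ft <- read.delim(file.path(dir, "features.tsv"), header = FALSE)
        if (nrow(ft) != nrow(counts) || nrow(bc) != ncol(counts))
            stop(sprintf(
                "MTX dimensions (%d x %d) disagree with features (%d) / barcodes (%d)",
                nrow(counts), ncol(counts), nrow(ft), nrow(bc)))
        # 10x features.tsv: column 2 is the gene symbol when present
        rownames(counts) <- as.character(ft[[min(2L, ncol(ft))]])
        colnames(counts) <- as.character(bc[[1]])
    }
    co <- readDelimAuto(coordsPath)
    if (ncol(co) >= 3 && !is.numeric(co[[1]])) {
        ids <- as.character(co[[1]])
        if (!setequal(ids, colnames(counts)))
            stop("coordinate spot ids do not match count spot ids")
        co <- co[match(colnames(counts), ids), , drop = FALSE]
        coords <- as.matrix(co[, 2:3])
    } else {
        if (nrow(co) != ncol(counts))
            stop(sprintf(
                "dimension mismatch: counts has %d spots but coords has %d rows",
                ncol(counts), nrow(co)))
        coords <- as.matrix(co[, seq_len(2)])
    }
    SpotExperiment(counts, coords)
}

readDelimAuto <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
    read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE)
}

#' Read a spots x cell-types weight matrix from CSV/TSV
#'
#' First column is the spot id; remaining columns are per-type weights
#' (typically deconvolution proportions summing to ~1 per spot).
#'
#' @param path file path.
#' @return numeric matrix, spots x types, rownames = spot ids.
#' @export
readCellTypeWeights <- function(path) {
    tab <- readDelimAuto(path)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- as.character(tab[[1]])
    m
}

#' Write a counts matrix as spots x genes CSV
#'
#' Round-trips exactly through [readSpotSample()] with `format = "csv"`.
#'
#' @param x a [SpotExperiment-class].
#' @param countsPath,coordsPath output paths.
#' @return invisibly, the two paths.
#' @export
writeSpotSample <- function(x, countsPath, coordsPath) {
    cts <- t(as.matrix(SummarizedExperiment::assay(x, "counts")))
    df <- data.frame(spot_id = rownames(cts), cts, check.names = FALSE)
    write.csv_ <- function(d, p) write.table(d, p, sep = ",", row.names = FALSE,
                                             quote = FALSE)
    write.csv_(df, countsPath)
    xy <- spatialCoords(x)
    write.csv_(data.frame(spot_id = rownames(xy), x = xy[, 1], y = xy[, 2]),
               coordsPath)
    invisible(c(countsPath, coordsPath))
}
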