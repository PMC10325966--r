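#' Construct an LRDatabase from a data.frame
#'
#' @param pairs data.frame (or DataFrame) with columns `pair_id`, `ligand`,
#'   `receptor` (subunits joined by "_" or "&", or CharacterList), `pathway`,
#'   `signalling_type`.
#' @param species,version_tag free-text provenance tags.
#' @return an [LRDatabase-class].
#' @export
LRDatabase <- function(pairs, species = "human", version_tag = "custom") {
    pairs <- as.data.frame(pairs)
    need <- c("pair_id", "ligand", "receptor", "pathway", "signalling_type")
    miss <- setdiff(need, colnames(pairs))
    if (length(miss))
        stop("missing required column(s): ", paste(miss, collapse = ", "))
    splitSub <- function(x) {
        if (is.list(x)) lapply(x, toupper)
        else strsplit(toupper(gsub("&", "_", as.character(x))), "_", fixed = TRUE)
    }
    lig <- splitSub(pairs$ligand)
    rec <- splitSub(pairs$receptor)
    lig <- lapply(lig, function(s) s[nzchar(s)])
    rec <- lapply(rec, function(s) s[nzchar(s)])
    empty <- lengths(lig) == 0 | lengths(rec) == 0
    if (any(empty)) {
        warning(sum(empty), " pair(s) with empty subunit list skipped")
        pairs <- pairs[!empty, , drop = FALSE]
        lig <- lig[!empty]; rec <- rec[!empty]
    }
    id <- as.character(pairs$pair_id)
    noId <- is.na(id) | !nzchar(id)
    if (any(noId))
        id[noId] <- paste(vapply(lig[noId], paste, "", collapse = "_"),
                          vapply(rec[noId], paste, "", collapse = "_"),
                          sep = "_")
    df <- S4Vectors::DataFrame(
        pair_id = id,
        ligand = IRanges::CharacterList(lig),
        receptor = IRanges::CharacterList(rec),
        pathway = as.character(pairs$pathway),
        signalling_type = as.character(pairs$signalling_type))
    new("LRDatabase", pairs = df, species = species, version_tag = version_tag)
}

#' Read a ligand-receptor database CSV
#'
#' Expects columns `pair_id`, `ligand`, `receptor`, `pathway`,
#' `signalling_type`; multi-subunit complexes are encoded by joining gene
#' symbols with "_" (or "&"). Symbols are uppercased. A header-only file
#' yields an empty database.
#'
#' @param path CSV/TSV file path.
#' @param species,version_tag provenance tags stored on the object.
#' @return an [LRDatabase-class].
#' @export
readLRDatabase <- function(path, species = "human", version_tag = basename(path)) {
    tab <- readDelimAuto(path)
    need <- c("pair_id", "ligand", "receptor", "pathway", "signalling_type")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("missing required column(s): ", paste(miss, collapse = ", "))
    LRDatabase(tab, species = species, version_tag = version_tag)
}

#' Pair table of a database or result
#'
#' @param x an [LRDatabase-class].
#' @return the pairs [S4Vectors::DataFrame].
#' @rdname lrPairs
#' @export
setMethod("lrPairs", "LRDatabase", function(x) x@pairs)

setMethod("show", "LRDatabase", function(object) {
    cat(sprintf("LRDatabase: %d pairs (%s, %s)\n", nrow(object@pairs),
                object@species, object@version_tag))
    st <- table(object@pairs$signalling_type)
    if (length(st))
        cat(" ", paste(sprintf("%s: %d", names(st), st), collapse = ", "), "\n")
})

#' Filter a database against the genes of a sample
#'
#' Matching is case-insensitive (both sides uppercased). In strict mode
#' (default) a pair is kept only if every ligand and receptor subunit is
#' present; otherwise pairs keep their available subunits and are dropped
#' only when a side loses all of them.
#'
#' @param db an [LRDatabase-class].
#' @param sample a [SpotExperiment-class].
#' @param strict drop pairs with any missing subunit (default TRUE).
#' @return the filtered [LRDatabase-class].
#' @export
filterDatabase <- function(db, sample, strict = TRUE) {
    genes <- toupper(rownames(sample))
    p <- db@pairs
    lig <- as.list(p$ligand); rec <- as.list(p$receptor)
    if (strict) {
        keep <- vapply(lig, function(s) all(s %in% genes), TRUE) &
                vapply(rec, function(s) all(s %in% genes), TRUE)
    } else {
        lig <- lapply(lig, intersect, genes)
        rec <- lapply(rec, intersect, genes)
        keep <- lengths(lig) > 0 & lengths(rec) > 0
        p$ligand <- IRanges::CharacterList(lig)
        p$receptor <- IRanges::CharacterList(rec)
    }
    new("LRDatabase", pairs = p[keep, ], species = db@species,
        version_tag = db@version_tag)
}

#' Shuffle a database into non-documented ligand-receptor pairs
#'
#' Builds a negative-control list by re-pairing the database's ligand
#' complexes with receptor complexes they are not documented to bind,
#' excluding any (ligand set, receptor set) combination present in the input.
#'
#' @param db an [LRDatabase-class] with >= 2 pairs.
#' @param nPairs number of shuffled pairs to draw.
#' @param seed integer seed (reproducible).
#' @return an [LRDatabase-class] of undocumented pairs; `pathway` is set to
#'   "shuffled" and the signalling type is inherited from the ligand's
#'   original record.
#' @export
shuffleDatabase <- function(db, nPairs, seed = 1) {
    p <- db@pairs
    if (nrow(p) < 2) stop("need at least 2 documented pairs to shuffle")
    ligKey <- subunitKey(p$ligand)
    recKey <- subunitKey(p$receptor)
    docKey <- paste(ligKey, recKey, sep = "|")
    uLig <- !duplicated(ligKey)
    uRec <- !duplicated(recKey)
    combo <- expand.grid(li = which(uLig), ri = which(uRec))
    comboKey <- paste(ligKey[combo$li], recKey[combo$ri], sep = "|")
    ok <- !comboKey %in% docKey
    if (sum(ok) < nPairs)
        stop(sprintf("requested %d pairs but only %d undocumented combinations exist",
                     nPairs, sum(ok)))
    pick <- withSeed(seed, sample(which(ok), nPairs))
    li <- combo$li[pick]; ri <- combo$ri[pick]
    lig <- as.list(p$ligand)[li]
    rec <- as.list(p$receptor)[ri]
    df <- S4Vectors::DataFrame(
        pair_id = make.unique(paste(vapply(lig, paste, "", collapse = "_"),
                                    vapply(rec, paste, "", collapse = "_"),
                                    sep = "_")),
        ligand = IRanges::CharacterList(lig),
        receptor = IRanges::CharacterList(rec),
        pathway = "shuffled",
        signalling_type = p$signalling_type[li])
    new("LRDatabase", pairs = df, species = db@species,
        version_tag = paste0(db@version_tag, "-shuffled"))
}
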