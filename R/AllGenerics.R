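#' @rdname spatialCoords
#' @export
setGeneric("spatialCoords", function(x) standardGeneric("spatialCoords"))

#' @rdname normalizeLog
#' @export
setGeneric("normalizeLog", function(x, scale = 1e4) standardGeneric("normalizeLog"))

#' @rdname weightsMatrix
#' @export
setGeneric("weightsMatrix", function(x) standardGeneric("weightsMatrix"))

#' @rdname lrPairs
#' @export
setGeneric("lrPairs", function(x) standardGeneric("lrPairs"))

#' @rdname globalResults
#' @export
setGeneric("globalResults", function(x) standardGeneric("globalResults"))

#' @rdname selectedPairs
#' @export
setGeneric("selectedPairs", function(x) standardGeneric("selectedPairs"))

#' @rdname hitsMatrix
#' @export
setGeneric("hitsMatrix", function(x) standardGeneric("hitsMatrix"))
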