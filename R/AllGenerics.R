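#' Accessors for tissuetalk classes
#'
#' `abundances()` returns the abundance matrix, `tissueName()` the tissue
#' label, `valueScale()` the scale of the stored values, `proteinIds()` and
#' `sampleIds()` the identifier vectors. `diffTable()` returns a
#' [DifferentialResult-class]'s per-protein table, `excludedProteins()` the
#' proteins dropped by filters, `significantProteins()` the identifiers with
#' `q < alpha`. `edgeCounts()`, `rawScore()` and `normalizedScore()` read a
#' [CrosstalkEdge-class]; `predictedTargets()` and `predictionRanking()` read
#' a [TargetPrediction-class].
#'
#' @param object a tissuetalk S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("abundances", function(object) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setGeneric("tissueName", function(object) standardGeneric("tissueName"))
#' @rdname accessors
#' @export
setGeneric("valueScale", function(object) standardGeneric("valueScale"))
#' @rdname accessors
#' @export
setGeneric("proteinIds", function(object) standardGeneric("proteinIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("diffTable", function(object) standardGeneric("diffTable"))
#' @rdname accessors
#' @export
setGeneric("excludedProteins", function(object) standardGeneric("excludedProteins"))
#' @rdname accessors
#' @export
setGeneric("significantProteins", function(object) standardGeneric("significantProteins"))
#' @rdname accessors
#' @export
setGeneric("edgeCounts", function(object) standardGeneric("edgeCounts"))
#' @rdname accessors
#' @export
setGeneric("rawScore", function(object) standardGeneric("rawScore"))
#' @rdname accessors
#' @export
setGeneric("normalizedScore", function(object) standardGeneric("normalizedScore"))
#' @rdname accessors
#' @export
setGeneric("predictedTargets", function(object) standardGeneric("predictedTargets"))
#' @rdname accessors
#' @export
setGeneric("predictionRanking", function(object) standardGeneric("predictionRanking"))

#' @rdname logTransform
#' @export
setGeneric("logTransform", function(object, pseudo = 1) standardGeneric("logTransform"))

#' @rdname significantFraction
#' @export
setGeneric("significantFraction", function(object) standardGeneric("significantFraction"))
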