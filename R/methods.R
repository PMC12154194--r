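#' @rdname accessors
#' @aliases abundances,TissueProteome-method
setMethod("abundances", "TissueProteome", function(object)
  assay(object, "abundance"))

#' @rdname accessors
setMethod("tissueName", "TissueProteome", function(object) object@tissue)

#' @rdname accessors
setMethod("valueScale", "TissueProteome", function(object) object@valueScale)

#' @rdname accessors
setMethod("proteinIds", "TissueProteome", function(object) rownames(object))

#' @rdname accessors
setMethod("sampleIds", "TissueProteome", function(object) colnames(object))

setMethod("show", "TissueProteome", function(object) {
  m <- abundances(object)
  cat(sprintf("TissueProteome: %s [%s scale]\n", object@tissue, object@valueScale))
  cat(sprintf("  %d proteins x %d samples; %d missing values (%.1f%%)\n",
              nrow(m), ncol(m), sum(is.na(m)),
              if (length(m)) 100 * mean(is.na(m)) else 0))
  if (ncol(colData(object)))
    cat("  sample annotation:", paste(colnames(colData(object)), collapse = ", "), "\n")
})

#' @rdname accessors
setMethod("diffTable", "DifferentialResult", function(object) object@table)

#' @rdname accessors
setMethod("excludedProteins", "DifferentialResult", function(object) object@excluded)

#' @rdname accessors
setMethod("significantProteins", "DifferentialResult", function(object)
  object@table$protein_id[object@table$significant])

setMethod("show", "DifferentialResult", function(object) {
  cat(sprintf("DifferentialResult: %s, %s vs %s\n", object@tissue,
              object@conditions[2L], object@conditions[1L]))
  cat(sprintf("  %d proteins tested, %d significant at q < %g; %d excluded\n",
              nrow(object@table), sum(object@table$significant), object@alpha,
              nrow(object@excluded)))
})

#' @rdname accessors
setMethod("edgeCounts", "CrosstalkEdge", function(object) object@counts)

#' @rdname accessors
setMethod("rawScore", "CrosstalkEdge", function(object) object@rawScore)

#' @rdname accessors
setMethod("normalizedScore", "CrosstalkEdge", function(object) object@normalizedScore)

setMethod("show", "CrosstalkEdge", function(object) {
  cat(sprintf("CrosstalkEdge: %s -> %s\n", object@origin, object@target))
  cat(sprintf("  raw score %g over %d secreted x %d target proteins (normalized %.4g)\n",
              object@rawScore, object@nSecretedTested, object@nTargetsTested,
              object@normalizedScore))
  if (!is.na(object@permP))
    cat(sprintf("  subject-permutation p = %.4g\n", object@permP))
})

#' @rdname accessors
setMethod("predictedTargets", "TargetPrediction", function(object) object@predictedSet)

#' @rdname accessors
setMethod("predictionRanking", "TargetPrediction", function(object) {
  r <- object@table$r
  names(r) <- object@table$target_protein
  r
})

setMethod("show", "TargetPrediction", function(object) {
  cat(sprintf("TargetPrediction: %s (%s) -> %s\n", object@candidate,
              object@originTissue, object@targetTissue))
  cat(sprintf("  %d target proteins screened, %d predicted at p < %g\n",
              nrow(object@table), length(object@predictedSet), object@alpha))
})
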