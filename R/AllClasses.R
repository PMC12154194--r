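#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata `metadata<-`
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData `assay<-` `rowData<-`
NULL

#' TissueProteome: a single tissue's protein abundance matrix
#'
#' An S4 container for one tissue's label-free quantification (LFQ) table,
#' proteins in rows and samples in columns, built on
#' [SummarizedExperiment::SummarizedExperiment]. The single assay is named
#' `"abundance"`. Missing quantifications are stored as `NA`, never as zero
#' (zero is a legitimate intensity). The object tracks which scale the values
#' are on: `"intensity"` (non-negative, arbitrary LFQ units) or `"log2"`
#' (after [logTransform()]).
#'
#' @slot tissue single tissue label (e.g. `"liver"`).
#' @slot valueScale `"intensity"` or `"log2"`.
#'
#' @seealso [TissueProteome()] for construction, [readAbundanceTable()],
#'   [logTransform()], [abundances()].
#' @export
setClass("TissueProteome",
  contains = "SummarizedExperiment",
  representation(tissue = "character", valueScale = "character")
)

setValidity("TissueProteome", function(object) {
  msg <- character()
  if (length(object@tissue) != 1L || is.na(object@tissue) || !nzchar(object@tissue))
    msg <- c(msg, "'tissue' must be a single non-empty label")
  if (length(object@valueScale) != 1L ||
      !object@valueScale %in% c("intensity", "log2"))
    msg <- c(msg, "'valueScale' must be \"intensity\" or \"log2\"")
  if (!"abundance" %in% assayNames(object))
    msg <- c(msg, "assay \"abundance\" is required")
  else {
    m <- assay(object, "abundance")
    if ((nrow(m) > 0L && is.null(rownames(m))) ||
        (ncol(m) > 0L && is.null(colnames(m))))
      msg <- c(msg, "protein and sample identifiers (dimnames) are required")
    else {
      if (anyDuplicated(rownames(m)))
        msg <- c(msg, "duplicated protein identifiers")
      if (anyDuplicated(colnames(m)))
        msg <- c(msg, "duplicated sample identifiers")
    }
    v <- m[!is.na(m)]
    if (any(!is.finite(v)))
      msg <- c(msg, "non-missing abundances must be finite")
    if (identical(object@valueScale, "intensity") && any(v < 0))
      msg <- c(msg, "intensity-scale abundances must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TissueProteome
#'
#' @param values numeric matrix, proteins in rows (rownames = protein IDs),
#'   samples in columns (colnames = sample IDs); `NA` marks missing values.
#' @param tissue single tissue label.
#' @param colData optional `DataFrame`/`data.frame` of per-sample annotation
#'   (rownames must match `colnames(values)`).
#' @param rowData optional per-protein annotation.
#' @param valueScale `"intensity"` (default) or `"log2"`.
#' @return a validated [TissueProteome-class] object.
#' @examples
#' m <- matrix(c(1, 2, 4, 8), 2, 2,
#'   dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' TissueProteome(m, tissue = "liver")
#' @export
TissueProteome <- function(values, tissue, colData = NULL, rowData = NULL,
                           valueScale = c("intensity", "log2")) {
  valueScale <- match.arg(valueScale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colData))
    colData <- DataFrame(row.names = colnames(values))
  se <- SummarizedExperiment(
    assays = SimpleList(abundance = values),
    colData = colData
  )
  if (!is.null(rowData))
    rowData(se) <- rowData
  new("TissueProteome", se, tissue = tissue, valueScale = valueScale)
}

#' Differential abundance result for one tissue and condition pair
#'
#' Holds the per-protein two-group statistics produced by
#' [differentialTable()]: log2 fold change of raw group means, equal-variance
#' Student t statistic and two-tailed p on log2 intensities, and
#' Benjamini-Hochberg adjusted q within the tissue. Proteins that fail the
#' complete-case filter or have zero pooled variance are listed in `excluded`
#' with a reason rather than being assigned degenerate p-values.
#'
#' @slot tissue tissue label.
#' @slot conditions length-2 character, `c(reference, treatment)`; fold
#'   changes are treatment over reference.
#' @slot alpha significance threshold applied to q.
#' @slot table data.frame with columns `protein_id`, `log2fc`, `t`, `p`, `q`,
#'   `n_a`, `n_b`, `significant`, sorted by q then p.
#' @slot excluded data.frame with columns `protein_id`, `reason`.
#' @seealso [differentialTable()], [significantFraction()], [concordance()]
#' @export
setClass("DifferentialResult",
  representation(tissue = "character", conditions = "character",
                 alpha = "numeric", table = "data.frame",
                 excluded = "data.frame")
)

setValidity("DifferentialResult", function(object) {
  msg <- character()
  if (length(object@conditions) != 2L)
    msg <- c(msg, "'conditions' must name exactly two groups")
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "'alpha' must lie in (0, 1)")
  need <- c("protein_id", "log2fc", "t", "p", "q", "n_a", "n_b", "significant")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, paste("table must have columns:", paste(need, collapse = ", ")))
  else {
    tb <- object@table
    if (anyDuplicated(tb$protein_id))
      msg <- c(msg, "one record per tested protein required")
    if (nrow(tb) && (any(tb$q < tb$p - 1e-12) || any(tb$q > 1 + 1e-12)))
      msg <- c(msg, "q must satisfy p <= q <= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Directed tissue-pair cross-talk edge
#'
#' One ordered tissue pair of the endocrine cross-talk network. For every
#' secreted protein tested in the origin tissue, `counts` records how many
#' target-tissue proteins it correlates with significantly across subjects;
#' `rawScore` is the sum of those counts and `normalizedScore` divides by the
#' number of (secreted, target) pairs tested so that tissue pairs with
#' different proteome sizes are comparable.
#'
#' @slot origin,target tissue labels, distinct.
#' @slot counts named integer vector, one entry per tested secreted protein.
#' @slot rawScore sum of `counts`.
#' @slot normalizedScore `rawScore / (nSecretedTested * nTargetsTested)`,
#'   in \[0, 1\].
#' @slot nSecretedTested,nTargetsTested numbers of proteins screened.
#' @slot permP optional subject-permutation empirical p (`NA` when not run).
#' @seealso [crosstalkScore()], [crosstalkNetwork()], [rankCandidates()]
#' @export
setClass("CrosstalkEdge",
  representation(origin = "character", target = "character",
                 counts = "integer", rawScore = "numeric",
                 normalizedScore = "numeric", nSecretedTested = "integer",
                 nTargetsTested = "integer", permP = "numeric")
)

setValidity("CrosstalkEdge", function(object) {
  msg <- character()
  if (identical(object@origin, object@target))
    msg <- c(msg, "origin and target tissue must differ")
  if (length(object@counts) &&
      !isTRUE(all.equal(object@rawScore, sum(object@counts))))
    msg <- c(msg, "rawScore must equal the sum of per-protein counts")
  if (object@normalizedScore < 0 || object@normalizedScore > 1)
    msg <- c(msg, "normalizedScore must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Predicted target program of a candidate secreted protein
#'
#' The per-target-protein signed correlation of a candidate secreted factor's
#' origin-tissue abundance with every protein of the target tissue, the subset
#' passing the significance rule (the predicted target set), and the full
#' signed-r vector usable as a preranked statistic for [prerankedGSEA()].
#'
#' @slot candidate secreted protein identifier.
#' @slot originTissue,targetTissue tissue labels.
#' @slot table data.frame with columns `target_protein`, `r`, `p`, `n`,
#'   `predicted`.
#' @slot predictedSet character vector, subset of the target tissue proteome.
#' @slot alpha significance threshold used.
#' @seealso [predictTargets()], [predictionRanking()]
#' @export
setClass("TargetPrediction",
  representation(candidate = "character", originTissue = "character",
                 targetTissue = "character", table = "data.frame",
                 predictedSet = "character", alpha = "numeric")
)

setValidity("TargetPrediction", function(object) {
  msg <- character()
  if (!all(object@predictedSet %in% object@table$target_protein))
    msg <- c(msg, "predictedSet must be a subset of the screened target proteome")
  if (length(msg)) msg else TRUE
})
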