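#' Log2-transform an abundance matrix
#'
#' Applies `log2(v + pseudo)` to every non-missing value; missing values stay
#' missing. With `pseudo = 0` and zeros present the transform is refused
#' (zero intensities would map to -Inf) and the caller is directed to set a
#' pseudo-count or filter.
#'
#' @param object a [TissueProteome-class] on the intensity scale.
#' @param pseudo non-negative offset added before the log (default 1).
#' @return a [TissueProteome-class] with `valueScale == "log2"`.
#' @rdname logTransform
#' @export
setMethod("logTransform", "TissueProteome", function(object, pseudo = 1) {
  if (!identical(valueScale(object), "intensity"))
    .stopf("matrix is already on the log2 scale")
  if (pseudo < 0) .stopf("'pseudo' must be >= 0")
  m <- abundances(object)
  if (pseudo == 0 && any(m == 0, na.rm = TRUE))
    .stopf("zero intensities present with pseudo = 0; set a pseudo-count or filter first")
  out <- object
  out@valueScale <- "log2"
  SummarizedExperiment::assay(out, "abundance") <- log2(m + pseudo)
  validObject(out)
  out
})

#' Unpaired equal-variance Student t test
#'
#' Classical two-sample Student t with pooled variance and
#' `df = n_x + n_y - 2`, two-tailed p. The statistic is
#' `(mean(x) - mean(y)) / se`. When the pooled variance is zero the test is
#' flagged degenerate (`t` and `p` are `NA`) rather than returning `p = 0`.
#'
#' @param x,y numeric vectors (NAs dropped); each needs >= 2 non-missing
#'   values.
#' @return list with `t_stat`, `p_value`, `df`, `n_x`, `n_y`, `degenerate`.
#' @examples
#' studentTTwoSample(c(1, 2, 3), c(4, 5, 6))$t_stat  # -3.674
#' @export
studentTTwoSample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    .stopf("each group needs >= 2 non-missing values (got %d and %d)",
           length(x), length(y))
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  df <- nx + ny - 2
  if (sp2 == 0)
    return(list(t_stat = NA_real_, p_value = NA_real_, df = df,
                n_x = nx, n_y = ny, degenerate = TRUE))
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t_stat = t, p_value = 2 * stats::pt(-abs(t), df), df = df,
       n_x = nx, n_y = ny, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: with order statistics `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1; the input order is
#' preserved in the output.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.5))
#' @export
benjaminiHochberg <- function(p) {
  if (!length(p)) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1))
    .stopf("p-values must lie in [0, 1] with no missing values")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * p[o]))
  q[order(o)]
}

#' Per-tissue differential abundance table
#'
#' For each protein with at least `minPerGroup` non-missing values per
#' condition: log2 fold change from the raw-intensity group means
#' (`log2(mean_treatment / mean_reference)`), equal-variance Student t and
#' two-tailed p on `log2(v + pseudo)` values, and BH q over all retained
#' proteins of the tissue (one multiple-testing family per tissue and
#' condition pair). Proteins failing the filter, or with zero pooled variance
#' on the log scale, are excluded and listed with a reason.
#'
#' @param object a [TissueProteome-class] on the intensity scale.
#' @param metadata sample metadata data.frame (columns `sample_id`,
#'   `condition`, ...); may be omitted when the object's `colData` carries a
#'   `condition` column.
#' @param conditions length-2 character `c(reference, treatment)`.
#' @param alpha significance threshold on q (default 0.05).
#' @param minPerGroup minimum non-missing values per group (default 3).
#' @param pseudo pseudo-count for the log transform (default 1).
#' @return a [DifferentialResult-class].
#' @export
differentialTable <- function(object, metadata = NULL, conditions,
                              alpha = 0.05, minPerGroup = 3L, pseudo = 1) {
  stopifnot(is(object, "TissueProteome"))
  if (length(conditions) != 2L)
    .stopf("'conditions' must be c(reference, treatment)")
  cond <- .sampleConditions(object, metadata)
  for (cc in conditions)
    if (!cc %in% cond) .stopf("condition '%s' has no samples in this tissue", cc)
  a <- sampleIds(object)[cond == conditions[1L]]
  b <- sampleIds(object)[cond == conditions[2L]]

  raw <- abundances(object)
  lg <- abundances(logTransform(object, pseudo = pseudo))
  sa <- .rowStats(lg[, a, drop = FALSE])
  sb <- .rowStats(lg[, b, drop = FALSE])

  keep <- sa$n >= minPerGroup & sb$n >= minPerGroup
  sp2 <- ((sa$n - 1) * sa$var + (sb$n - 1) * sb$var) / (sa$n + sb$n - 2)
  degen <- keep & (is.na(sp2) | sp2 == 0)
  tested <- keep & !degen

  excluded <- rbind(
    data.frame(protein_id = proteinIds(object)[!keep],
               reason = rep(sprintf("fewer than %d non-missing values per group",
                                    minPerGroup), sum(!keep)),
               stringsAsFactors = FALSE),
    data.frame(protein_id = proteinIds(object)[degen],
               reason = rep("degenerate variance", sum(degen)),
               stringsAsFactors = FALSE)
  )

  ids <- proteinIds(object)[tested]
  df <- sa$n[tested] + sb$n[tested] - 2
  tstat <- (sb$mean[tested] - sa$mean[tested]) /
    sqrt(sp2[tested] * (1 / sa$n[tested] + 1 / sb$n[tested]))
  pval <- 2 * stats::pt(-abs(tstat), df)
  meanA <- rowMeans(raw[tested, a, drop = FALSE], na.rm = TRUE)
  meanB <- rowMeans(raw[tested, b, drop = FALSE], na.rm = TRUE)
  lfc <- log2(meanB / meanA)
  qval <- benjaminiHochberg(pval)

  tb <- data.frame(protein_id = ids, log2fc = unname(lfc), t = unname(tstat),
                   p = unname(pval), q = unname(qval),
                   n_a = unname(sa$n[tested]), n_b = unname(sb$n[tested]),
                   significant = unname(qval < alpha),
                   stringsAsFactors = FALSE)
  tb <- tb[order(tb$q, tb$p, tb$protein_id), , drop = FALSE]
  rownames(tb) <- NULL
  new("DifferentialResult", tissue = tissueName(object),
      conditions = as.character(conditions), alpha = alpha, table = tb,
      excluded = excluded)
}

.sampleConditions <- function(object, metadata) {
  if (!is.null(metadata)) {
    i <- match(sampleIds(object), metadata$sample_id)
    if (anyNA(i))
      .stopf("samples missing from metadata: %s",
             paste(utils::head(sampleIds(object)[is.na(i)], 3L), collapse = ", "))
    metadata$condition[i]
  } else if ("condition" %in% colnames(colData(object))) {
    colData(object)$condition
  } else {
    .stopf("no sample conditions: supply 'metadata' or a 'condition' colData column")
  }
}

#' Fraction of the tested proteome called significant
#'
#' `count(q < alpha) / count(tested)` for a [DifferentialResult-class] — the
#' per-tissue summary used to compare the extent of proteome remodeling
#' across tissues.
#'
#' @param object a [DifferentialResult-class].
#' @return a single fraction in \[0, 1\].
#' @rdname significantFraction
#' @export
setMethod("significantFraction", "DifferentialResult", function(object) {
  if (!nrow(object@table)) .stopf("empty differential table")
  mean(object@table$significant)
})

#' Cross-perturbation overlap and directional concordance
#'
#' Compares two differential tables (e.g. the same tissue under two distinct
#' perturbations): counts of significant proteins in each, the overlap
#' (significant in both), how many overlapping proteins move in opposite
#' directions, and the Pearson correlation of the two log2 fold-change
#' vectors over the overlap.
#'
#' @param tableA,tableB [DifferentialResult-class] objects sharing (part of)
#'   a protein universe.
#' @return one-row data.frame with columns `n_sig_a`, `n_sig_b`, `n_overlap`,
#'   `frac_overlap_of_b`, `n_opposite`, `frac_opposite`, `fc_correlation`
#'   (`NA` when the overlap is empty).
#' @export
concordance <- function(tableA, tableB) {
  stopifnot(is(tableA, "DifferentialResult"), is(tableB, "DifferentialResult"))
  sigA <- significantProteins(tableA)
  sigB <- significantProteins(tableB)
  ov <- intersect(sigA, sigB)
  fcA <- stats::setNames(tableA@table$log2fc, tableA@table$protein_id)[ov]
  fcB <- stats::setNames(tableB@table$log2fc, tableB@table$protein_id)[ov]
  nOpp <- sum(sign(fcA) != sign(fcB))
  data.frame(
    n_sig_a = length(sigA), n_sig_b = length(sigB), n_overlap = length(ov),
    frac_overlap_of_b = if (length(sigB)) length(ov) / length(sigB) else NA_real_,
    n_opposite = nOpp,
    frac_opposite = if (length(ov)) nOpp / length(ov) else NA_real_,
    fc_correlation = if (length(ov) >= 2L &&
                         stats::sd(fcA) > 0 && stats::sd(fcB) > 0)
      stats::cor(fcA, fcB) else NA_real_
  )
}
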