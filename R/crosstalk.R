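#' Pair two tissues' samples by subject
#'
#' Cross-tissue correlations are computed across mice, so samples of the two
#' tissues must be paired by subject. Returns the ordered list of subjects
#' measured in both tissues (optionally restricted to one condition) with the
#' matching sample identifiers.
#'
#' @param matrixA,matrixB [TissueProteome-class] objects for the two tissues.
#' @param metadata sample metadata data.frame (`sample_id`, `subject_id`,
#'   `tissue`, `condition`).
#' @param scope `"all"` to pool both conditions (default) or one condition
#'   label.
#' @param minPairs minimum number of common subjects (default 5; below that
#'   correlation p-values are meaningless).
#' @return data.frame with columns `subject_id`, `sample_a`, `sample_b`,
#'   `condition`.
#' @export
alignSubjects <- function(matrixA, matrixB, metadata, scope = "all",
                          minPairs = 5L) {
  md <- metadata
  if (!identical(scope, "all")) {
    if (!scope %in% md$condition)
      .stopf("scope condition '%s' absent from metadata", scope)
    md <- md[md$condition == scope, , drop = FALSE]
  }
  mdA <- md[md$tissue == tissueName(matrixA) &
              md$sample_id %in% sampleIds(matrixA), , drop = FALSE]
  mdB <- md[md$tissue == tissueName(matrixB) &
              md$sample_id %in% sampleIds(matrixB), , drop = FALSE]
  common <- intersect(mdA$subject_id, mdB$subject_id)
  if (length(common) < minPairs)
    .stopf("only %d subjects measured in both %s and %s (need >= %d)",
           length(common), tissueName(matrixA), tissueName(matrixB), minPairs)
  common <- sort(common)
  ia <- match(common, mdA$subject_id)
  ib <- match(common, mdB$subject_id)
  data.frame(subject_id = common, sample_a = mdA$sample_id[ia],
             sample_b = mdB$sample_id[ib], condition = mdA$condition[ia],
             stringsAsFactors = FALSE)
}

# Correlation matrix with per-pair n and two-tailed p from the exact
# t transform t = r sqrt(n-2) / sqrt(1-r^2). Spearman rank-transforms first
# and applies the same t approximation.
.corWithP <- function(X, Y, method) {
  if (method == "spearman") {
    X <- t(apply(X, 1L, rank, ties.method = "average", na.last = "keep"))
    Y <- t(apply(Y, 1L, rank, ties.method = "average", na.last = "keep"))
  }
  r <- suppressWarnings(stats::cor(t(X), t(Y),
                                   use = "pairwise.complete.obs"))
  n <- tcrossprod((!is.na(X)) * 1, (!is.na(Y)) * 1)
  tt <- r * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tt), pmax(n - 2, 1))
  p[!is.na(r) & abs(r) == 1] <- 0
  list(r = r, n = n, p = p)
}

#' Screen secreted-protein correlations between two tissues
#'
#' For every secreted protein s quantified in the origin tissue and every
#' protein t of the target tissue, computes the correlation of their log2
#' abundances across the paired subjects and a two-tailed p; records with
#' `p < alpha` are flagged significant. This is the elementary screen behind
#' the directional cross-talk score: a secreted protein correlating with
#' many proteins of another tissue may signal the need for those changes.
#'
#' @param matrixA origin-tissue [TissueProteome-class] (intensity or log2
#'   scale; intensities are log2-transformed with `pseudo`).
#' @param matrixB target-tissue [TissueProteome-class].
#' @param secreted character vector of secreted protein identifiers.
#' @param pairing subject pairing from [alignSubjects()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param alpha nominal two-tailed significance threshold (default 0.05).
#' @param minPairs minimum non-missing pairs per correlation (default 5).
#' @param pseudo pseudo-count for the log transform of intensity-scale input.
#' @return data.frame of correlation records: `origin_protein`,
#'   `target_protein`, `r`, `p_value`, `n`, `significant`; pairs with a
#'   zero-variance vector or fewer than `minPairs` complete pairs are
#'   dropped and counted in `attr(, "skipped")`.
#' @export
correlationScreen <- function(matrixA, matrixB, secreted, pairing,
                              method = c("pearson", "spearman"),
                              alpha = 0.05, minPairs = 5L, pseudo = 1) {
  method <- match.arg(method)
  if (nrow(pairing) < minPairs)
    .stopf("pairing has %d subjects; need >= %d", nrow(pairing), minPairs)
  sec <- intersect(secreted, proteinIds(matrixA))
  if (!length(sec))
    .stopf("no secreted protein quantified in %s", tissueName(matrixA))
  la <- if (identical(valueScale(matrixA), "log2")) matrixA
        else logTransform(matrixA, pseudo = pseudo)
  lb <- if (identical(valueScale(matrixB), "log2")) matrixB
        else logTransform(matrixB, pseudo = pseudo)
  X <- abundances(la)[sec, pairing$sample_a, drop = FALSE]
  Y <- abundances(lb)[, pairing$sample_b, drop = FALSE]
  cw <- .corWithP(X, Y, method)
  long <- data.frame(
    origin_protein = rep(rownames(X), times = nrow(Y)),
    target_protein = rep(rownames(Y), each = nrow(X)),
    r = as.vector(cw$r), p_value = as.vector(cw$p),
    n = as.integer(as.vector(cw$n)),
    stringsAsFactors = FALSE)
  ok <- !is.na(long$r) & long$n >= minPairs
  skipped <- long[!ok, c("origin_protein", "target_protein", "n")]
  skipped$reason <- ifelse(is.na(long$r[!ok]), "zero variance or no overlap",
                           "fewer pairs than minPairs")
  long <- long[ok, , drop = FALSE]
  long$significant <- long$p_value < alpha
  rownames(long) <- NULL
  attr(long, "skipped") <- skipped
  attr(long, "n_secreted_tested") <- nrow(X)
  attr(long, "n_targets_tested") <- nrow(Y)
  long
}

#' Sum a correlation screen into a directed cross-talk edge
#'
#' Per origin (secreted) protein, counts the significantly correlating
#' target proteins; the raw edge score is the sum of those counts and the
#' normalized score divides by the number of (secreted, target) pairs tested
#' so edges between tissues of different proteome sizes are comparable.
#'
#' @param records correlation records from [correlationScreen()].
#' @param origin,target tissue labels of the edge.
#' @param nSecretedTested,nTargetsTested numbers of proteins screened;
#'   defaults are taken from the attributes [correlationScreen()] attaches.
#' @return a [CrosstalkEdge-class].
#' @export
crosstalkScore <- function(records, origin, target,
                           nSecretedTested = attr(records, "n_secreted_tested"),
                           nTargetsTested = attr(records, "n_targets_tested")) {
  if (is.null(nSecretedTested) || nSecretedTested == 0L)
    .stopf("no secreted proteins tested for edge %s -> %s", origin, target)
  tested <- unique(records$origin_protein)
  counts <- stats::setNames(integer(length(tested)), tested)
  if (nrow(records)) {
    tab <- table(records$origin_protein[records$significant])
    counts[names(tab)] <- as.integer(tab)
  }
  raw <- sum(counts)
  new("CrosstalkEdge", origin = origin, target = target, counts = counts,
      rawScore = as.numeric(raw),
      normalizedScore = raw / (as.numeric(nSecretedTested) * nTargetsTested),
      nSecretedTested = as.integer(nSecretedTested),
      nTargetsTested = as.integer(nTargetsTested), permP = NA_real_)
}

#' Directional cross-talk network over all tissue pairs
#'
#' Runs [alignSubjects()], [correlationScreen()] and [crosstalkScore()] for
#' every ordered pair of tissues (A -> B, A != B) and summarizes per-origin
#' totals (the "strength of all cross-talk originating from that tissue").
#' Pairs that cannot be paired (too few common subjects, no secreted protein
#' quantified) are reported, not fatal.
#'
#' An optional subject-permutation null attaches an empirical p to each
#' edge: the pairing between the two tissues is shuffled `nPermutations`
#' times and `perm_p = (1 + #{raw_perm >= raw}) / (nPermutations + 1)`.
#'
#' @param proteomes named list of [TissueProteome-class] objects.
#' @param metadata sample metadata data.frame.
#' @param secreted secreted-protein identifiers.
#' @param method,alpha,minPairs,pseudo,scope passed to the per-pair screen.
#' @param nPermutations subject permutations per edge (0 = skip, default).
#' @param seed seed for the permutation null.
#' @return list with `edges` (data.frame: `origin`, `target`, `raw_score`,
#'   `normalized_score`, `n_secreted_tested`, `n_targets_tested`, `perm_p`),
#'   `edgeObjects` (list of [CrosstalkEdge-class] keyed `"A->B"`),
#'   `originTotals` (data.frame of summed normalized scores per origin) and
#'   `failures` (data.frame: `origin`, `target`, `reason`).
#' @export
crosstalkNetwork <- function(proteomes, metadata, secreted,
                             method = c("pearson", "spearman"), alpha = 0.05,
                             minPairs = 5L, pseudo = 1, scope = "all",
                             nPermutations = 0L, seed = 1L) {
  method <- match.arg(method)
  if (length(proteomes) < 2L) .stopf("need >= 2 tissues")
  tissues <- names(proteomes)
  edges <- list(); objs <- list(); fails <- list()
  for (a in tissues) for (b in tissues) {
    if (a == b) next
    key <- paste0(a, "->", b)
    res <- tryCatch({
      pairing <- alignSubjects(proteomes[[a]], proteomes[[b]], metadata,
                               scope = scope, minPairs = minPairs)
      rec <- correlationScreen(proteomes[[a]], proteomes[[b]], secreted,
                               pairing, method = method, alpha = alpha,
                               minPairs = minPairs, pseudo = pseudo)
      edge <- crosstalkScore(rec, a, b)
      if (nPermutations > 0L)
        edge@permP <- .edgePermutationP(proteomes[[a]], proteomes[[b]],
                                        secreted, pairing, method, alpha,
                                        minPairs, pseudo, edge@rawScore,
                                        nPermutations,
                                        .deriveSeed(seed, length(objs) + 1L))
      edge
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      fails[[key]] <- data.frame(origin = a, target = b, reason = res,
                                 stringsAsFactors = FALSE)
    } else {
      objs[[key]] <- res
      edges[[key]] <- data.frame(
        origin = a, target = b, raw_score = res@rawScore,
        normalized_score = res@normalizedScore,
        n_secreted_tested = res@nSecretedTested,
        n_targets_tested = res@nTargetsTested, perm_p = res@permP,
        stringsAsFactors = FALSE)
    }
  }
  edgeDf <- if (length(edges)) do.call(rbind, unname(edges)) else
    data.frame(origin = character(), target = character(),
               raw_score = numeric(), normalized_score = numeric(),
               n_secreted_tested = integer(), n_targets_tested = integer(),
               perm_p = numeric())
  totals <- if (nrow(edgeDf))
    stats::aggregate(cbind(total_normalized = normalized_score,
                           total_raw = raw_score) ~ origin, edgeDf, sum)
  else data.frame(origin = character(), total_normalized = numeric(),
                  total_raw = numeric())
  list(edges = edgeDf, edgeObjects = objs,
       originTotals = totals[order(-totals$total_normalized), , drop = FALSE],
       failures = if (length(fails)) do.call(rbind, unname(fails)) else
         data.frame(origin = character(), target = character(),
                    reason = character()))
}

.edgePermutationP <- function(ma, mb, secreted, pairing, method, alpha,
                              minPairs, pseudo, observedRaw, nPerm, seed) {
  withr::with_seed(as.integer(seed), {
    raws <- vapply(seq_len(nPerm), function(b) {
      perm <- pairing
      perm$sample_b <- sample(perm$sample_b)
      rec <- correlationScreen(ma, mb, secreted, perm, method = method,
                               alpha = alpha, minPairs = minPairs,
                               pseudo = pseudo)
      crosstalkScore(rec, "a", "b")@rawScore
    }, numeric(1L))
    (1 + sum(raws >= observedRaw)) / (nPerm + 1)
  })
}

#' Rank candidate secreted factors of an edge
#'
#' Candidates are ranked by the product of two ranks: the rank of their mean
#' origin-tissue abundance (descending; expression in the origin tissue) and
#' the rank of their per-protein significant-correlation count (descending;
#' strength of predicted effects in the target tissue). A smaller rank
#' product is a stronger candidate. Ties in either component use mid-ranks;
#' ties in the product are broken lexicographically by protein identifier.
#'
#' @param edge a [CrosstalkEdge-class].
#' @param originMatrix the origin tissue's [TissueProteome-class] (intensity
#'   scale; mean log2 abundance is used).
#' @param pseudo pseudo-count for the log transform.
#' @return data.frame with columns `protein_id`, `count`,
#'   `origin_abundance_rank`, `effect_rank`, `rank_product`, `final_rank`,
#'   sorted by `final_rank`; empty (with a warning) when every count is zero.
#' @export
rankCandidates <- function(edge, originMatrix, pseudo = 1) {
  stopifnot(is(edge, "CrosstalkEdge"), is(originMatrix, "TissueProteome"))
  counts <- edge@counts
  if (!length(counts) || all(counts == 0)) {
    warning("all candidate counts are zero; empty ranking")
    return(data.frame(protein_id = character(), count = integer(),
                      origin_abundance_rank = numeric(),
                      effect_rank = numeric(), rank_product = numeric(),
                      final_rank = integer()))
  }
  la <- if (identical(valueScale(originMatrix), "log2")) originMatrix
        else logTransform(originMatrix, pseudo = pseudo)
  ab <- rowMeans(abundances(la)[names(counts), , drop = FALSE], na.rm = TRUE)
  abundanceRank <- rank(-ab, ties.method = "average")
  effectRank <- rank(-counts, ties.method = "average")
  rp <- abundanceRank * effectRank
  o <- order(rp, names(counts))
  out <- data.frame(protein_id = names(counts)[o],
                    count = as.integer(counts[o]),
                    origin_abundance_rank = unname(abundanceRank[o]),
                    effect_rank = unname(effectRank[o]),
                    rank_product = unname(rp[o]),
                    final_rank = seq_along(o), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Predict the target program of a candidate secreted factor
#'
#' Correlates the candidate's origin-tissue log2 abundance with every
#' protein of the target tissue across the paired subjects. Targets with
#' `p < alpha` form the predicted set; the full signed-r vector (via
#' [predictionRanking()]) is a preranked statistic suitable for
#' [prerankedGSEA()], giving the pathway program the candidate is predicted
#' to drive.
#'
#' @param candidate secreted protein identifier, present in `originMatrix`.
#' @param originMatrix,targetMatrix [TissueProteome-class] objects.
#' @param pairing subject pairing from [alignSubjects()].
#' @param method `"pearson"` or `"spearman"`.
#' @param alpha significance threshold on the correlation p (default 0.05).
#' @param minPairs minimum complete pairs per correlation.
#' @param pseudo pseudo-count for the log transform.
#' @return a [TargetPrediction-class].
#' @export
predictTargets <- function(candidate, originMatrix, targetMatrix, pairing,
                           method = c("pearson", "spearman"), alpha = 0.05,
                           minPairs = 5L, pseudo = 1) {
  method <- match.arg(method)
  if (!candidate %in% proteinIds(originMatrix))
    .stopf("candidate '%s' not quantified in %s", candidate,
           tissueName(originMatrix))
  rec <- correlationScreen(originMatrix, targetMatrix, candidate, pairing,
                           method = method, alpha = alpha,
                           minPairs = minPairs, pseudo = pseudo)
  tb <- data.frame(target_protein = rec$target_protein, r = rec$r,
                   p = rec$p_value, n = rec$n, predicted = rec$significant,
                   stringsAsFactors = FALSE)
  new("TargetPrediction", candidate = candidate,
      originTissue = tissueName(originMatrix),
      targetTissue = tissueName(targetMatrix), table = tb,
      predictedSet = tb$target_protein[tb$predicted], alpha = alpha)
}
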