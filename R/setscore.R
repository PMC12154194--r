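#' Single-sample gene-set score (standardized mean rank)
#'
#' Per-sample "browning score"-style statistic: within each sample, all N
#' proteins are ranked by abundance (ascending, ties mid-rank) and the score
#' is the standardized mean rank of the K set members,
#' `(meanRank - (N+1)/2) / sqrt((N+1)(N-K) / (12 K))`,
#' which has mean 0 and unit variance under random set membership. Being
#' rank-based, the score is invariant to any monotone transform of a
#' sample's abundances, so depots/samples can be compared ordinally. This is
#' a deliberately simple alternative to kernel-CDF single-sample enrichment
#' (GSVA-style) scores.
#'
#' @param object a [TissueProteome-class] with no missing values in the
#'   scored samples (filter first).
#' @param geneSet character vector of member identifiers; members absent
#'   from the matrix are dropped (an error is raised if none is present).
#' @param setName label recorded in the output.
#' @return data.frame with columns `sample_id`, `set_name`, `score`.
#' @export
sampleSetScore <- function(object, geneSet, setName = "set") {
  stopifnot(is(object, "TissueProteome"))
  m <- abundances(object)
  if (anyNA(m))
    .stopf("matrix contains missing values; filter to complete cases first")
  members <- intersect(unique(geneSet), rownames(m))
  if (!length(members))
    .stopf("no set member detected in the matrix; missing: %s",
           paste(utils::head(unique(geneSet), 10L), collapse = ", "))
  N <- nrow(m); K <- length(members)
  scores <- vapply(seq_len(ncol(m)), function(j) {
    r <- rank(m[, j], ties.method = "average")
    if (K == N) return(0)  # mean rank forced to (N+1)/2
    (mean(r[members]) - (N + 1) / 2) /
      sqrt((N + 1) * (N - K) / (12 * K))
  }, numeric(1L))
  data.frame(sample_id = colnames(m), set_name = setName, score = scores,
             stringsAsFactors = FALSE)
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score on a ranking
# sorted descending. isMember: logical along the sorted ranking.
.runningSumES <- function(statsSorted, isMember) {
  N <- length(statsSorted)
  K <- sum(isMember)
  w <- abs(statsSorted)
  sumw <- sum(w[isMember])
  if (sumw == 0)
    .stopf("all set-member statistics are zero; enrichment score undefined")
  if (K == N)
    .stopf("gene set covers the whole ranking; no outside steps to walk")
  step <- ifelse(isMember, w / sumw, -1 / (N - K))
  cs <- cumsum(step)
  hi <- max(cs); lo <- min(cs)
  # the positive extremum wins ties in magnitude (within rounding)
  if (hi >= -lo - 1e-9) hi else lo
}

#' Preranked gene-set enrichment with a permutation null
#'
#' Classic weighted running-sum enrichment: the ranking is sorted by its
#' statistic descending; walking down it, the running sum increases by
#' `|s_i| / sum_set |s|` at set members and decreases by `1/(N-K)` otherwise;
#' the enrichment score ES is the signed maximum deviation (in \[-1, 1\]).
#' The null is built by permuting gene labels (drawing random K-subsets of
#' the ranking): `NES = ES / mean(|ES_perm|)` over same-sign permutations and
#' `p_perm = (1 + #{same-sign |ES_perm| >= |ES|}) / (n_same_sign + 1)`.
#'
#' @param ranking named numeric vector (protein -> statistic), no missing
#'   values; e.g. t statistics or the signed correlations from
#'   [predictionRanking()].
#' @param geneSet character vector of member identifiers; the intersection
#'   with the ranking is used and must be non-empty.
#' @param nPermutations gene-label permutations (default 1000).
#' @param seed integer seed making the permutation p reproducible.
#' @param setName label recorded in the output.
#' @return data.frame with one row: `set_name`, `es`, `nes`, `p_perm`,
#'   `n_permutations`, `seed`, `size`.
#' @examples
#' r <- c(a = 3, b = 2, c = 1, d = -1, e = -2)
#' prerankedGSEA(r, c("a", "c"), nPermutations = 100, seed = 1)$es  # 0.75
#' @export
prerankedGSEA <- function(ranking, geneSet, nPermutations = 1000L,
                          seed = 1L, setName = "set") {
  if (is.null(names(ranking)) || anyNA(ranking))
    .stopf("'ranking' must be a named numeric vector without missing values")
  if (all(ranking == 0)) .stopf("all ranking statistics are zero")
  members <- intersect(unique(geneSet), names(ranking))
  if (!length(members)) .stopf("gene set does not intersect the ranking")
  ord <- order(ranking, names(ranking), decreasing = TRUE)
  s <- ranking[ord]
  isMember <- names(s) %in% members
  es <- .runningSumES(s, isMember)
  N <- length(s); K <- length(members)
  perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(nPermutations), function(b) {
      mem <- logical(N)
      mem[sample.int(N, K)] <- TRUE
      tryCatch(.runningSumES(s, mem), error = function(e) NA_real_)
    }, numeric(1L))
  })
  perm <- perm[!is.na(perm)]
  same <- perm[sign(perm) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  pPerm <- (1 + sum(abs(same) >= abs(es))) / (length(same) + 1)
  data.frame(set_name = setName, es = es, nes = nes, p_perm = pPerm,
             n_permutations = as.integer(nPermutations),
             seed = as.integer(seed), size = K, stringsAsFactors = FALSE)
}

#' Hypergeometric overrepresentation test with an explicit background
#'
#' Tests whether a query protein set overlaps a gene set more than expected
#' by chance within a stated background (the tissue's detected proteome, so
#' that enrichment intrinsic to the tissue's function is corrected for). The
#' query is intersected with the background and the gene set is restricted
#' to the background before counting;
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)` (upper tail including
#' the observed overlap). With several sets, q-values are BH-adjusted across
#' the tested sets.
#'
#' @param query character vector of proteins of interest (e.g. significantly
#'   regulated proteins).
#' @param geneSets one character vector or a named list of them (e.g. from
#'   [readGMT()]).
#' @param background character vector: the protein universe.
#' @return data.frame with columns `set_name`, `k_hits`, `n_query`,
#'   `K_set_in_background`, `N_background`, `p_hyper`, `q_value`.
#' @export
overrepresentationTest <- function(query, geneSets, background) {
  if (!length(background)) .stopf("empty background")
  if (!is.list(geneSets)) geneSets <- list(set = geneSets)
  background <- unique(background)
  query <- intersect(unique(query), background)
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(geneSets), function(nm) {
    K <- length(intersect(unique(geneSets[[nm]]), background))
    k <- length(intersect(query, geneSets[[nm]]))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k_hits = k, n_query = n,
               K_set_in_background = K, N_background = N, p_hyper = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- benjaminiHochberg(out$p_hyper)
  out
}
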