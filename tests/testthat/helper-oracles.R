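# Independent oracles used to cross-check the package's statistics. Each is
# a deliberately naive implementation (explicit loops / enumeration) kept
# separate from the code paths it checks.

# BH step-up by its definition: q_(i) = min_{j >= i} p_(j) * m / j, capped.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) qs[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- qs
  out
}

# Hand-walked weighted running sum; same extremum convention as the package
# (positive deviation wins exact-tie magnitude) but computed stepwise.
esOracle <- function(ranking, members) {
  ord <- order(ranking, names(ranking), decreasing = TRUE)
  s <- ranking[ord]
  hit <- names(s) %in% members
  N <- length(s)
  K <- sum(hit)
  sumw <- sum(abs(s)[hit])
  cur <- 0
  hi <- -Inf
  lo <- Inf
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) abs(s[i]) / sumw else -1 / (N - K)
    hi <- max(hi, cur)
    lo <- min(lo, cur)
  }
  if (hi >= -lo - 1e-9) hi else lo
}

# Exact hypergeometric upper tail by enumeration of combinations.
oraOracle <- function(k, K, N, n) {
  js <- k:min(n, K)
  js <- js[js >= max(0, n - (N - K))]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Brute-force double-loop correlation screen via cor.test.
screenOracle <- function(matA, matB, secreted, pairing, alpha = 0.05,
                         pseudo = 1) {
  la <- log2(abundances(matA)[, pairing$sample_a, drop = FALSE] + pseudo)
  lb <- log2(abundances(matB)[, pairing$sample_b, drop = FALSE] + pseudo)
  sec <- intersect(secreted, rownames(la))
  rows <- list()
  for (s in sec) for (t in rownames(lb)) {
    ct <- suppressWarnings(stats::cor.test(la[s, ], lb[t, ]))
    rows[[paste(s, t)]] <- data.frame(
      origin_protein = s, target_protein = t,
      r = unname(ct$estimate), p_value = ct$p.value,
      n = sum(!is.na(la[s, ]) & !is.na(lb[t, ])),
      significant = ct$p.value < alpha, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  out
}
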