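mkPair <- function(nSubj = 6, nA = 8, nB = 10, seed = 3, tissueA = "liver",
                   tissueB = "sWAT") {
  set.seed(seed)
  subj <- sprintf("m%d", seq_len(nSubj))
  mkTp <- function(tissue, nProt) {
    m <- matrix(2^rnorm(nProt * nSubj, 20, 1), nProt, nSubj,
                dimnames = list(sprintf("%s%02d", substr(tissue, 1, 1), seq_len(nProt)),
                                paste(tissue, subj, sep = "_")))
    TissueProteome(m, tissue)
  }
  md <- do.call(rbind, lapply(c(tissueA, tissueB), function(t)
    data.frame(sample_id = paste(t, subj, sep = "_"), subject_id = subj,
               tissue = t, condition = rep(c("tn", "cold"), length.out = nSubj),
               stringsAsFactors = FALSE)))
  list(a = mkTp(tissueA, nA), b = mkTp(tissueB, nB), md = md, subj = subj)
}

test_that("subject pairing respects scope and the minimum-pairs rule", {
  px <- mkPair(nSubj = 6)
  pairing <- alignSubjects(px$a, px$b, px$md)
  expect_identical(nrow(pairing), 6L)
  expect_identical(pairing$sample_a, paste("liver", pairing$subject_id, sep = "_"))
  cold <- alignSubjects(px$a, px$b, px$md, scope = "cold", minPairs = 3)
  expect_true(all(cold$condition == "cold"))
  expect_identical(nrow(cold), 3L)
  # disjoint subject sets cannot be paired
  mdDisj <- px$md
  mdDisj$subject_id[mdDisj$tissue == "sWAT"] <-
    paste0("x", mdDisj$subject_id[mdDisj$tissue == "sWAT"])
  expect_error(alignSubjects(px$a, px$b, mdDisj), "0 subjects")
  expect_error(alignSubjects(px$a, px$b, px$md, scope = "hot"), "absent")
})

test_that("the correlation screen equals the brute-force double loop", {
  px <- mkPair(nSubj = 8, nA = 20, nB = 30, seed = 5)
  pairing <- alignSubjects(px$a, px$b, px$md)
  secreted <- proteinIds(px$a)[1:7]
  mine <- correlationScreen(px$a, px$b, secreted, pairing)
  oracle <- screenOracle(px$a, px$b, secreted, pairing)
  key <- function(d) d[order(d$origin_protein, d$target_protein), ]
  mine <- key(mine); oracle <- key(oracle)
  expect_equal(mine$r, oracle$r, tolerance = 1e-12)
  expect_equal(mine$p_value, oracle$p_value, tolerance = 1e-12)
  expect_identical(mine$significant, oracle$significant)
  expect_identical(mine$n, as.integer(oracle$n))
})

test_that("a perfect driver copy correlates at r = 1 and is flagged", {
  px <- mkPair(nSubj = 6, seed = 7)
  m <- abundances(px$b)
  m["s01", ] <- abundances(px$a)["l01", ]   # noiseless planted target
  b2 <- TissueProteome(m, "sWAT")
  rec <- correlationScreen(px$a, b2, "l01",
                           alignSubjects(px$a, b2, px$md))
  hit <- rec[rec$target_protein == "s01", ]
  expect_equal(hit$r, 1, tolerance = 1e-12)
  expect_true(hit$significant)
})

test_that("zero-variance targets are skipped with a reason, not scored", {
  px <- mkPair(nSubj = 6, seed = 9)
  m <- abundances(px$b)
  m["s02", ] <- 5
  b2 <- TissueProteome(m, "sWAT")
  rec <- correlationScreen(px$a, b2, c("l01", "l02"),
                           alignSubjects(px$a, b2, px$md))
  expect_false("s02" %in% rec$target_protein)
  sk <- attr(rec, "skipped")
  expect_true(all(sk$target_protein == "s02"))
  expect_match(sk$reason[1], "variance")
})

test_that("edge scores sum counts and normalize by the tested pair count", {
  rec <- data.frame(
    origin_protein = rep(c("A", "B", "C"), each = 4),
    target_protein = rep(sprintf("t%d", 1:4), 3),
    r = 0.5, p_value = 0.01, n = 6,
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                    FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  attr(rec, "n_secreted_tested") <- 3L
  attr(rec, "n_targets_tested") <- 4L
  e <- crosstalkScore(rec, "liver", "sWAT")
  expect_identical(unname(edgeCounts(e)[c("A", "B", "C")]), c(4L, 1L, 2L))
  expect_equal(rawScore(e), 7)
  expect_equal(normalizedScore(e), 7 / 12)
  # record order invariance
  e2 <- crosstalkScore(rec[sample(nrow(rec)), ], "liver", "sWAT",
                       nSecretedTested = 3L, nTargetsTested = 4L)
  expect_equal(rawScore(e2), rawScore(e))
  # saturated screen hits the normalization upper bound
  recAll <- rec; recAll$significant <- TRUE
  expect_equal(normalizedScore(crosstalkScore(recAll, "liver", "sWAT",
                                              3L, 4L)), 1)
  # no significant records
  recNone <- rec; recNone$significant <- FALSE
  expect_equal(rawScore(crosstalkScore(recNone, "liver", "sWAT", 3L, 4L)), 0)
  # doubling the target universe with no new signal halves the normalized score
  eWide <- crosstalkScore(rec, "liver", "sWAT", 3L, 8L)
  expect_equal(normalizedScore(eWide), normalizedScore(e) / 2)
  expect_equal(rawScore(eWide), rawScore(e))
  expect_error(crosstalkScore(rec, "liver", "sWAT", 0L, 4L), "no secreted")
})

test_that("the network scores every ordered pair and survives unpairable tissues", {
  sim <- simulateCohort(cohortSpec(tissues = c("liver", "sWAT", "eWAT"),
                                   proteinsPerTissue = 30,
                                   nSubjectsPerCondition = 5,
                                   fracRegulated = 0, seed = 19))
  net <- crosstalkNetwork(sim$proteomes, sim$metadata, sim$secreted)
  expect_identical(nrow(net$edges), 6L)   # M(M-1) ordered pairs
  expect_identical(nrow(net$failures), 0L)
  expect_setequal(net$originTotals$origin, c("liver", "sWAT", "eWAT"))
  # make one tissue unpairable: its failures are reported, others scored
  md2 <- sim$metadata
  md2$subject_id[md2$tissue == "eWAT"] <- paste0("z", md2$subject_id[md2$tissue == "eWAT"])
  net2 <- crosstalkNetwork(sim$proteomes, md2, sim$secreted)
  expect_identical(nrow(net2$edges), 2L)
  expect_identical(nrow(net2$failures), 4L)
})

test_that("candidate ranking multiplies abundance and effect ranks with ID tie-breaks", {
  counts <- c(A = 5L, B = 5L, C = 0L)
  edge <- new("CrosstalkEdge", origin = "liver", target = "sWAT",
              counts = counts, rawScore = 10, normalizedScore = 10 / 30,
              nSecretedTested = 3L, nTargetsTested = 10L, permP = NA_real_)
  m <- matrix(2^c(10, 10, 10, 12, 12, 12, 8, 8, 8), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  rk <- rankCandidates(edge, TissueProteome(m, "liver"))
  # B leads on abundance, ties A on effect; C is last on both
  expect_identical(rk$protein_id, c("B", "A", "C"))
  expect_identical(rk$final_rank, 1:3)
  # identical ranks everywhere: lexicographic order on protein ID
  mTie <- matrix(2^10, 3, 3, dimnames = dimnames(m))
  rkTie <- rankCandidates(edge, TissueProteome(mTie, "liver"))
  expect_identical(rkTie$protein_id[1:2], c("A", "B"))
  # all-zero counts give an empty ranking with a warning
  edge0 <- new("CrosstalkEdge", origin = "liver", target = "sWAT",
               counts = c(A = 0L, B = 0L), rawScore = 0, normalizedScore = 0,
               nSecretedTested = 2L, nTargetsTested = 10L, permP = NA_real_)
  expect_warning(rk0 <- rankCandidates(edge0, TissueProteome(m[1:2, ], "liver")),
                 "zero")
  expect_identical(nrow(rk0), 0L)
})

test_that("target prediction recovers a noise-free planted module exactly", {
  sim <- simulateCohort(cohortSpec(tissues = c("liver", "sWAT"),
                                   proteinsPerTissue = 50,
                                   nSubjectsPerCondition = 6,
                                   fracRegulated = 0, seed = 29),
                        plantedEdge("liver", "sWAT", moduleSize = 8,
                                    moduleNoiseSd = 0))
  ed <- sim$truth$edges[[1]]
  pairing <- alignSubjects(sim$proteomes$liver, sim$proteomes$sWAT, sim$metadata)
  pred <- predictTargets(ed$driverProtein, sim$proteomes$liver,
                         sim$proteomes$sWAT, pairing)
  expect_true(all(ed$targetModule %in% predictedTargets(pred)))
  expect_true(all(predictedTargets(pred) %in% proteinIds(sim$proteomes$sWAT)))
  expect_error(predictTargets("nope", sim$proteomes$liver,
                              sim$proteomes$sWAT, pairing), "not quantified")
  # the signed-r ranking feeds preranked enrichment: the planted module
  # scores a strong positive ES
  enr <- prerankedGSEA(predictionRanking(pred), ed$targetModule,
                       nPermutations = 200, seed = 3,
                       setName = "planted_module")
  expect_gt(enr$es, 0.5)
  expect_lt(enr$p_perm, 0.05)
})

test_that("subject-permutation nulls attach a small p to a real edge", {
  sim <- recoveryCohort(seed = 31, nProteins = 60, nPer = 8, rTarget = 0.9,
                        moduleSize = 20)
  net <- crosstalkNetwork(sim$proteomes, sim$metadata, sim$secreted,
                          nPermutations = 49, seed = 2)
  fwd <- net$edges[net$edges$origin == "liver" & net$edges$target == "sWAT", ]
  expect_lte(fwd$perm_p, 0.05)
  expect_gte(fwd$perm_p, 1 / 50)
  # determinism of the permutation p
  net2 <- crosstalkNetwork(sim$proteomes, sim$metadata, sim$secreted,
                           nPermutations = 49, seed = 2)
  expect_identical(net$edges$perm_p, net2$edges$perm_p)
})
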