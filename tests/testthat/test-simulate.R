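test_that("the generator is a pure function of spec and edges", {
  spec <- cohortSpec(tissues = c("liver", "sWAT"), proteinsPerTissue = 30,
                     nSubjectsPerCondition = 4, seed = 5)
  edge <- plantedEdge("liver", "sWAT", moduleSize = 5)
  a <- simulateCohort(spec, edge)
  b <- simulateCohort(spec, edge)
  expect_identical(lapply(a$proteomes, abundances),
                   lapply(b$proteomes, abundances))
  expect_identical(a$truth, b$truth)
  c <- simulateCohort(cohortSpec(tissues = c("liver", "sWAT"),
                                 proteinsPerTissue = 30,
                                 nSubjectsPerCondition = 4, seed = 6), edge)
  expect_false(identical(abundances(a$proteomes$liver),
                         abundances(c$proteomes$liver)))
})

test_that("cohort spec and edge invariants are enforced", {
  expect_error(cohortSpec(tissues = "liver"), ">= 2")
  expect_error(cohortSpec(fracRegulated = 1.2), "\\[0, 1\\]")
  expect_error(cohortSpec(noiseSd = 0), "> 0")
  expect_error(plantedEdge("liver", "liver"), "must differ")
  expect_error(
    simulateCohort(cohortSpec(tissues = c("liver", "sWAT")),
                   plantedEdge("liver", "brain", moduleSize = 3)),
    "unknown tissue")
})

test_that("zero regulated fraction yields empty truth and exchangeable groups", {
  sim <- simulateNullCohort(cohortSpec(tissues = c("liver", "sWAT"),
                                       proteinsPerTissue = 200,
                                       nSubjectsPerCondition = 8, seed = 2))
  expect_true(all(vapply(sim$truth$regulated, nrow, 1L) == 0L))
  expect_length(sim$truth$edges, 0L)
  # law of large numbers: per-protein group mean differences center on zero
  lg <- log2(abundances(sim$proteomes$liver))
  cond <- sim$metadata$condition[match(colnames(lg), sim$metadata$sample_id)]
  diffs <- rowMeans(lg[, cond == "cold_5C"]) -
    rowMeans(lg[, cond == "thermoneutral_30C"])
  expect_lt(abs(mean(diffs)), 3 * 0.25 / sqrt(8 * 200))
})

test_that("planted condition effects are recovered within sampling tolerance", {
  spec <- cohortSpec(tissues = c("liver", "sWAT"), proteinsPerTissue = 100,
                     nSubjectsPerCondition = 8, fracRegulated = 0.4,
                     noiseSd = 0.2, seed = 9)
  sim <- simulateCohort(spec)
  truth <- sim$truth$regulated$liver
  lg <- log2(abundances(sim$proteomes$liver))
  cond <- sim$metadata$condition[match(colnames(lg), sim$metadata$sample_id)]
  est <- rowMeans(lg[truth$protein_id, cond == "cold_5C", drop = FALSE]) -
    rowMeans(lg[truth$protein_id, cond == "thermoneutral_30C", drop = FALSE])
  # each estimate has sd noiseSd * sqrt(2/n); 4 sigma covers the max over
  # all regulated proteins
  expect_true(all(abs(est - truth$log2fc) < 4 * spec$noiseSd * sqrt(2 / 8)))
})

test_that("a noise-free planted edge gives |r| = 1 with the coupling's sign", {
  spec <- cohortSpec(tissues = c("liver", "sWAT"), proteinsPerTissue = 40,
                     nSubjectsPerCondition = 5, fracRegulated = 0, seed = 11)
  for (beta in c(1, -2)) {
    sim <- simulateCohort(spec,
                          plantedEdge("liver", "sWAT", moduleSize = 6,
                                      couplingBeta = beta, moduleNoiseSd = 0))
    ed <- sim$truth$edges[[1]]
    d <- log2(abundances(sim$proteomes$liver))[ed$driverProtein, ]
    subj <- sub(".*_", "", names(d))
    tmat <- log2(abundances(sim$proteomes$sWAT))
    for (t in ed$targetModule) {
      r <- cor(d, tmat[t, paste0("sWAT_", subj)])
      expect_equal(abs(r), 1, tolerance = 1e-10)
      expect_identical(sign(r), sign(beta))
    }
  }
})

test_that("missing-at-random injection hits roughly the configured rate", {
  sim <- simulateCohort(cohortSpec(tissues = c("liver", "sWAT"),
                                   proteinsPerTissue = 300,
                                   nSubjectsPerCondition = 8,
                                   missingRate = 0.1, seed = 13))
  rate <- mean(is.na(abundances(sim$proteomes$liver)))
  expect_gt(rate, 0.07)
  expect_lt(rate, 0.13)
})

test_that("null-cohort p-values are approximately uniform", {
  sim <- simulateNullCohort(cohortSpec(tissues = c("liver", "sWAT"),
                                       proteinsPerTissue = 2000,
                                       nSubjectsPerCondition = 8, seed = 17))
  d <- differentialTable(sim$proteomes$liver, sim$metadata,
                         conditions = c("thermoneutral_30C", "cold_5C"))
  ks <- suppressWarnings(ks.test(diffTable(d)$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})
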