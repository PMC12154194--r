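test_that("log transform maps values as documented and keeps missing missing", {
  tp <- TissueProteome(
    matrix(c(8, 0, NA, 3), 2, 2, dimnames = list(c("P1", "P2"), c("s1", "s2"))),
    tissue = "liver")
  lt <- logTransform(tp, pseudo = 0 + 1)
  expect_identical(valueScale(lt), "log2")
  expect_equal(abundances(lt)["P2", "s1"], 0)   # log2(0 + 1)
  expect_true(is.na(abundances(lt)["P1", "s2"]))
  lt0 <- logTransform(TissueProteome(
    matrix(8, 1, 1, dimnames = list("P1", "s1")), "liver"), pseudo = 0)
  expect_equal(abundances(lt0)[1, 1], 3)        # log2(8)
  expect_error(logTransform(tp, pseudo = 0), "pseudo")
  expect_error(logTransform(lt), "already")
})

test_that("the Student t matches its closed form and the stats oracle", {
  # identical groups
  same <- studentTTwoSample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  # frozen closed-form case: mean diff -3, pooled sd 1, se = sqrt(2/3)
  r <- studentTTwoSample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t_stat, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$t_stat, -3.674, tolerance = 1e-3)
  expect_equal(r$p_value, 0.0213, tolerance = 1e-3)
  expect_identical(r$df, 4)
  # random cases against stats::t.test (independent route)
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1), mean = runif(1, -1, 1))
    mine <- studentTTwoSample(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  # degenerate variance is flagged, never p = 0
  deg <- studentTTwoSample(c(5, 5), c(5, 5))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))
  expect_error(studentTTwoSample(1, c(1, 2)), ">= 2")
})

test_that("swapping the groups flips t and preserves p", {
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(6, 0.5)
    a <- studentTTwoSample(x, y)
    b <- studentTTwoSample(y, x)
    expect_equal(a$t_stat, -b$t_stat, tolerance = 1e-14)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-14)
  }
})

test_that("BH adjustment matches the step-up definition and stays in order", {
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_identical(benjaminiHochberg(1.0), 1.0)
  expect_equal(benjaminiHochberg(rep(0.2, 7)), rep(0.2, 7))
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(21)
  for (i in 1:50) {
    p <- runif(sample(c(1, 2, 10, 100), 1))
    q <- benjaminiHochberg(p)
    expect_equal(q, bhOracle(p), tolerance = 1e-14)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-14)
    expect_true(all(q >= p - 1e-15))
    # monotone non-decreasing on the sorted scale
    expect_true(!is.unsorted(q[order(p)]))
  }
})

test_that("differential tables compute fold changes from raw means and filter honestly", {
  # log2fc = log2(8/2) = 2 exactly, from raw group means
  m <- rbind(P1 = c(1, 2, 3, 7, 8, 9),
             P2 = c(10, 11, 12, 10.5, 11.5, 12.5),
             P3 = c(5, 5, 5, 5, 5, 5),            # degenerate variance
             P4 = c(4, NA, NA, 6, 7, 8))           # fails min-per-group
  colnames(m) <- sprintf("s%d", 1:6)
  md <- data.frame(sample_id = colnames(m), subject_id = sprintf("m%d", 1:6),
                   tissue = "liver",
                   condition = rep(c("tn", "cold"), each = 3),
                   stringsAsFactors = FALSE)
  d <- differentialTable(TissueProteome(m, "liver"), md,
                         conditions = c("tn", "cold"), pseudo = 0)
  tb <- diffTable(d)
  expect_setequal(tb$protein_id, c("P1", "P2"))
  expect_equal(tb$log2fc[tb$protein_id == "P1"], 2)
  ex <- excludedProteins(d)
  expect_identical(ex$reason[ex$protein_id == "P3"], "degenerate variance")
  expect_match(ex$reason[ex$protein_id == "P4"], "non-missing")
  expect_error(differentialTable(TissueProteome(m, "liver"), md,
                                 conditions = c("tn", "hot")),
               "no samples")
})

test_that("planted strong effects reach significance at study-scale n", {
  spec <- cohortSpec(tissues = c("liver", "sWAT"), proteinsPerTissue = 150,
                     nSubjectsPerCondition = 8, fracRegulated = 0.2,
                     noiseSd = 0.2, seed = 23)
  sim <- simulateCohort(spec)
  d <- differentialTable(sim$proteomes$liver, sim$metadata,
                         conditions = spec$conditions)
  tb <- diffTable(d)
  truth <- sim$truth$regulated$liver
  strong <- truth$protein_id[abs(truth$log2fc) >= 1]
  expect_true(all(tb$significant[match(strong, tb$protein_id)]))
  # estimated sign matches the planted sign for strong effects
  expect_identical(sign(tb$log2fc[match(strong, tb$protein_id)]),
                   sign(truth$log2fc[match(strong, truth$protein_id)]))
  expect_equal(significantFraction(d), mean(tb$significant))
})

test_that("concordance counts overlap and opposite regulation as defined", {
  mk <- function(ids, lfc, sig) {
    n <- length(ids)
    new("DifferentialResult", tissue = "sWAT", conditions = c("a", "b"),
        alpha = 0.05,
        table = data.frame(protein_id = ids, log2fc = lfc, t = lfc,
                           p = ifelse(sig, 0.001, 0.5),
                           q = ifelse(sig, 0.01, 0.6), n_a = n, n_b = n,
                           significant = sig, stringsAsFactors = FALSE),
        excluded = data.frame(protein_id = character(),
                              reason = character()))
  }
  a <- mk(c("P1", "P2", "P3", "P4"), c(1, 2, -1, 3), c(TRUE, TRUE, TRUE, FALSE))
  b <- mk(c("P1", "P2", "P3", "P4"), c(-1, -2, -1, 3), c(TRUE, TRUE, TRUE, TRUE))
  cc <- concordance(a, b)
  expect_identical(cc$n_overlap, 3L)
  expect_identical(cc$n_opposite, 2L)
  expect_equal(cc$frac_opposite, 2 / 3)
  expect_equal(cc$frac_overlap_of_b, 3 / 4)
  expect_true(cc$n_overlap <= min(cc$n_sig_a, cc$n_sig_b))

  self <- concordance(a, a)
  expect_equal(self$frac_opposite, 0)
  expect_equal(self$fc_correlation, 1)

  noSig <- mk("P1", 1, FALSE)
  empty <- concordance(a, noSig)
  expect_identical(empty$n_overlap, 0L)
  expect_true(is.na(empty$fc_correlation))
})
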