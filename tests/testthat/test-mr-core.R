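test_that("Wald ratio arithmetic and error contract", {
  expect_equal(waldRatio(1, 0.1, 0.3, 0.1), list(beta = 0.3, se = 0.1))
  w <- waldRatio(0.5, 0.05, 0.2, 0.05)
  expect_equal(w$beta, 0.4)
  expect_equal(w$se, 0.1)
  w2 <- waldRatio(0.5, 0.05, 0.2, 0.05, seMethod = "second_order")
  expect_equal(w2$se, sqrt(0.05^2 / 0.25 + 0.04 * 0.0025 / 0.0625))
  expect_error(waldRatio(0, 0.1, 0.3, 0.1), "zero")
})

test_that("IVW is the fixed-effect precision-weighted mean", {
  one <- ivw(0.37, 0.12)
  expect_equal(one$beta, 0.37)
  expect_equal(one$se, 0.12)
  two <- ivw(c(0.4, 0.6), c(0.1, 0.1))
  expect_equal(two$beta, 0.5)
  expect_equal(two$se, 0.1 / sqrt(2), tolerance = 1e-9)
  k <- 5
  many <- ivw(rep(0.3, k), rep(0.2, k))
  expect_equal(many$beta, 0.3)
  expect_equal(many$se, 0.2 / sqrt(k))
  expect_error(ivw(numeric(), numeric()), "at least one")
})

test_that("multiple-testing thresholds reproduce the study's values", {
  thr <- multipleTestingThresholds(6849, 13)
  expect_equal(signif(thr@bonferroni, 3), 7.30e-6)
  expect_equal(signif(thr@suggestive, 3), 9.49e-5)
  expect_equal(thr@suggestive, thr@bonferroni * 13)
  both <- multipleTestingThresholds(1, 1)
  expect_equal(both@bonferroni, 0.05)
  expect_equal(both@suggestive, 0.05)
  expect_error(multipleTestingThresholds(0, 13), ">= 1")
})

test_that("MR result fields satisfy the OR/CI/P invariants exactly", {
  ins <- new("Instrument", geneId = "G1", tissue = "brain",
             records = records(mkSumStats(c("rs1", "rs2"), c(0.5, 0.45),
                                          c(0.04, 0.05))),
             clumpR2 = 0.01, pThreshold = 5e-8)
  out <- mkSumStats(c("rs1", "rs2"), c(0.21, 0.18), c(0.04, 0.05),
                    traitId = "glioma", traitType = "binary",
                    nCase = 500, nControl = 500, n = 1000)
  mr <- mrForInstrument(ins, out, subtype = "all_glioma")
  expect_identical(mr@method, "ivw")
  expect_equal(mr@or, exp(mr@beta), tolerance = 1e-12)
  expect_equal(mr@ciLow, exp(mr@beta - 1.959964 * mr@se), tolerance = 1e-12)
  expect_equal(mr@ciHigh, exp(mr@beta + 1.959964 * mr@se), tolerance = 1e-12)
  expect_equal(mr@pval, 2 * pnorm(-abs(mr@beta / mr@se)), tolerance = 1e-12)
  # a single-SNP instrument reduces to the Wald ratio
  ins1 <- new("Instrument", geneId = "G1", tissue = "brain",
              records = records(mkSumStats("rs1", 0.5, 0.04)),
              clumpR2 = 0.01, pThreshold = 5e-8)
  mr1 <- mrForInstrument(ins1, out)
  expect_identical(mr1@method, "wald_ratio")
  expect_equal(mr1@beta, 0.21 / 0.5)
  # zero outcome effect: OR 1, P 1
  out0 <- mkSumStats("rs1", 0, 0.04, traitId = "o")
  mr0 <- mrForInstrument(ins1, out0)
  expect_equal(mr0@or, 1)
  expect_equal(mr0@pval, 1)
  expect_error(mrForInstrument(ins, mkSumStats("rs9", 0.1, 0.1)),
               "missing from outcome")
})

test_that("printed OR/CI reconstruct the published Wald P values", {
  # OR 0.57 (0.44, 0.74) and 0.46 (0.32, 0.67): implied two-sided P
  expect_equal(pFromORCI(0.57, 0.44, 0.74), 2.20e-5, tolerance = 0.10)
  expect_equal(pFromORCI(0.46, 0.32, 0.67), 4.30e-5, tolerance = 0.10)
})

test_that("Wald estimates recover the causal effect on shared-variant data", {
  reps <- sharedVariantReps(200)
  expect_lt(abs(mean(reps$wald) - 0.4), 0.05)
})

test_that("MR P values are uniform under the null scenario", {
  ld <- simulateLDMatrix(10, 0.8, 10)
  sc <- simScenario("null", nExposure = 1000L, nCase = 1000L,
                    nControl = 1000L)
  pv <- vapply(1:200, function(i) {
    p <- simulateStudyPair(sc, ld, seed = 6000 + i)
    ex <- records(p$exposure); ou <- records(p$outcome)
    w <- waldRatio(ex$beta[5], ex$se[5], ou$beta[5], ou$se[5])
    2 * pnorm(-abs(w$beta / w$se))
  }, numeric(1))
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})
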