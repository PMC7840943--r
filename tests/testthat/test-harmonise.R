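test_that("identical allele coding passes through untouched", {
  ex <- mkSumStats(c("rs1", "rs2"), c(0.5, 0.3), c(0.05, 0.05))
  ou <- mkSumStats(c("rs1", "rs2"), c(0.2, -0.1), c(0.03, 0.03),
                   traitId = "out")
  hp <- harmonise(ex, ou)
  expect_equal(records(hp@outcome)$beta, c(0.2, -0.1))
  expect_equal(nrow(hp@dropped), 0L)
})

test_that("swapped alleles flip the outcome beta and frequency", {
  ex <- mkSumStats("rs1", 0.5, 0.05, ea = "A", oa = "G", eaf = 0.3)
  ou <- mkSumStats("rs1", 0.2, 0.03, ea = "G", oa = "A", eaf = 0.7,
                   traitId = "out")
  hp <- harmonise(ex, ou)
  expect_equal(records(hp@outcome)$beta, -0.2)
  expect_equal(records(hp@outcome)$eaf, 0.3)
  expect_identical(records(hp@outcome)$ea, "A")
})

test_that("strand-complementary codings are reconciled", {
  ex <- mkSumStats("rs1", 0.5, 0.05, ea = "A", oa = "G", eaf = 0.3)
  # T/C is the strand complement of A/G, same orientation
  ou <- mkSumStats("rs1", 0.2, 0.03, ea = "T", oa = "C", eaf = 0.3,
                   traitId = "out")
  hp <- harmonise(ex, ou)
  expect_equal(records(hp@outcome)$beta, 0.2)
  # C/T: complement with swapped orientation -> flip
  ou2 <- mkSumStats("rs1", 0.2, 0.03, ea = "C", oa = "T", eaf = 0.7,
                    traitId = "out")
  hp2 <- harmonise(ex, ou2)
  expect_equal(records(hp2@outcome)$beta, -0.2)
})

test_that("ambiguous palindromic SNPs are dropped, clear ones aligned", {
  ex <- mkSumStats("rs1", 0.5, 0.05, ea = "A", oa = "T", eaf = 0.49)
  ou <- mkSumStats("rs1", 0.2, 0.03, ea = "A", oa = "T", eaf = 0.51,
                   traitId = "out")
  # both EAFs within 0.08 of 0.5 -> ambiguous; pair has no other SNPs
  expect_error(harmonise(ex, ou), "no harmonisable")
  ex2 <- mkSumStats(c("rs1", "rs2"), c(0.5, 0.4), c(0.05, 0.05),
                    ea = "A", oa = "T", eaf = c(0.49, 0.2))
  ou2 <- mkSumStats(c("rs1", "rs2"), c(0.2, 0.1), c(0.03, 0.03),
                    ea = "A", oa = "T", eaf = c(0.51, 0.8),
                    traitId = "out")
  hp <- harmonise(ex2, ou2)
  expect_identical(hp@dropped$reason[hp@dropped$snp == "rs1"],
                   "palindromic, ambiguous")
  # rs2: frequencies on opposite sides of 0.5 -> aligned by flipping
  expect_equal(records(hp@outcome)$beta, -0.1)
  expect_equal(records(hp@outcome)$eaf, 0.2)
})

test_that("irreconcilable allele pairs are dropped with a reason", {
  ex <- mkSumStats(c("rs1", "rs2"), c(0.5, 0.4), c(0.05, 0.05),
                   ea = "A", oa = "G")
  ou <- mkSumStats(c("rs1", "rs2"), c(0.2, 0.1), c(0.03, 0.03),
                   ea = c("A", "A"), oa = c("C", "G"), traitId = "out")
  hp <- harmonise(ex, ou)
  expect_identical(hp@dropped$reason[hp@dropped$snp == "rs1"],
                   "allele mismatch")
  expect_identical(records(hp@exposure)$snp, "rs2")
})

test_that("harmonisation is idempotent and preserves |beta/se|", {
  set.seed(42)
  k <- 8
  ex <- mkSumStats(sprintf("rs%d", 1:k), rnorm(k), runif(k, 0.02, 0.2),
                   ea = "A", oa = "G", eaf = runif(k, 0.05, 0.95))
  swap <- rep(c(TRUE, FALSE), length.out = k)
  ou <- mkSumStats(sprintf("rs%d", 1:k), rnorm(k), runif(k, 0.02, 0.2),
                   ea = ifelse(swap, "G", "A"), oa = ifelse(swap, "A", "G"),
                   eaf = runif(k, 0.05, 0.95), traitId = "out")
  zBefore <- abs(records(ou)$beta / records(ou)$se)
  hp <- harmonise(ex, ou)
  zAfter <- abs(records(hp@outcome)$beta / records(hp@outcome)$se)
  expect_equal(sort(zAfter), sort(zBefore), tolerance = 1e-12)
  hp2 <- harmonise(hp@exposure, hp@outcome)
  expect_equal(records(hp2@outcome), records(hp@outcome))
  expect_equal(nrow(hp2@dropped), 0L)
})

test_that("disjoint SNP sets raise an empty-intersection error", {
  ex <- mkSumStats("rs1", 0.5, 0.05)
  ou <- mkSumStats("rs2", 0.2, 0.03, traitId = "out")
  expect_error(harmonise(ex, ou), "no shared SNPs")
})
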