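test_that("AR(1) block LD matrices have the stated structure", {
  expect_equal(ldr(simulateLDMatrix(5, 0, 5)), diag(5),
               ignore_attr = TRUE)
  expect_equal(ldr(simulateLDMatrix(4, 0.8, 4))[1, 3], 0.64)
  ld <- simulateLDMatrix(30, 0.9, 10)
  r <- ldr(ld)
  expect_equal(r[1, 11], 0)           # across blocks
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 30))
  # PSD by the eigen-decomposition oracle, over several geometries
  for (cfg in list(c(12, 0.95, 4), c(25, 0.5, 25), c(7, 0.99, 7))) {
    ev <- eigen(ldr(simulateLDMatrix(cfg[1], cfg[2], cfg[3])),
                symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
  expect_error(simulateLDMatrix(5, 1.0, 5), "rho")
  expect_error(simulateLDMatrix(5, 0.5, 6), "blockSize")
})

test_that("scenario invariants are enforced at construction", {
  expect_error(simScenario("distinct_variants", causalSnpExposure = 3L,
                           causalSnpOutcome = 3L), "distinct")
  expect_error(simScenario("shared_variant"), "causalSnpExposure")
  expect_error(simScenario("null", mafRange = c(0.1, 0.6)), "mafRange")
  expect_error(simScenario("wrong"), "name")
  sc <- simScenario("shared_variant", causalSnpExposure = 99L)
  expect_error(simulateStudyPair(sc, simulateLDMatrix(10, 0.5, 10), 1),
               "outside")
})

test_that("identical seeds give byte-identical simulated studies", {
  ld <- simulateLDMatrix(12, 0.7, 6)
  sc <- simScenario("shared_variant", causalSnpExposure = 3L,
                    nExposure = 200L, nCase = 150L, nControl = 150L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- writeStudyPair(simulateStudyPair(sc, ld, seed = 11), d1)
  f2 <- writeStudyPair(simulateStudyPair(sc, ld, seed = 11), d2)
  for (k in names(f1))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
  p3 <- simulateStudyPair(sc, ld, seed = 12)
  expect_false(identical(records(p3$exposure)$beta,
                         records(simulateStudyPair(sc, ld, 11)$exposure)$beta))
})

test_that("marginal Z-scores of neighbours track the LD with the causal SNP", {
  ld <- simulateLDMatrix(5, 0.8, 5)
  # MAF fixed at 0.3 so cross-replicate Z correlations reflect LD alone,
  # not shared non-centrality variation from per-replicate MAF draws
  sc <- simScenario("exposure_only", causalSnpExposure = 1L,
                    nExposure = 2000L, nCase = 100L, nControl = 100L,
                    mafRange = c(0.3, 0.3))
  z <- t(sapply(1:150, function(i) {
    rec <- records(simulateStudyPair(sc, ld, seed = 3000 + i)$exposure)
    rec$beta / rec$se
  }))
  # correlation of the marginal Z at a neighbour with the causal Z ~ r
  expect_lt(abs(cor(z[, 1], z[, 2]) - 0.8), 0.1)
  expect_lt(abs(cor(z[, 1], z[, 4]) - 0.8^3), 0.1)
})

test_that("null scenario is calibrated: exposure P < 0.05 about 5% of the time", {
  ld <- simulateLDMatrix(10, 0.8, 10)
  sc <- simScenario("null", nExposure = 1000L, nCase = 1000L,
                    nControl = 1000L)
  frac <- vapply(1:200, function(i)
    mean(records(simulateStudyPair(sc, ld, seed = 4000 + i)$exposure)$pval
         < 0.05), numeric(1))
  expect_lte(abs(mean(frac) - 0.05), 0.02 + 1e-12)
})

test_that("multi-tissue panel supports shared and discordant effects", {
  ld <- simulateLDMatrix(8, 0.6, 8)
  pan <- simulateMultitissuePanel(5, ld, seed = 5, causalSnp = 4L)
  expect_length(pan$sumstats, 5)
  expect_true(all(pan$betaGx == 0.5))
  expect_length(pan$expression, 5)
  # a sign-flipped tissue is flagged by the Z-discordance detector
  pan2 <- simulateMultitissuePanel(7, ld, seed = 6, causalSnp = 4L,
                                   betaGx = c(rep(0.5, 6), -0.5),
                                   sharedExposureEffect = FALSE)
  b <- vapply(pan2$sumstats, function(s) records(s)$beta[4], numeric(1))
  s <- vapply(pan2$sumstats, function(s) records(s)$se[4], numeric(1))
  expect_identical(tissueZDiscordance(pan2$tissues, b, s), "tissue07")
  # one-hot expression vector scores tau = 1 by definition
  pan3 <- simulateMultitissuePanel(4, ld, seed = 7,
                                   expression = c(3, 0, 0, 0))
  expect_equal(tauScore(pan3$expression)$tau, 1)
  expect_error(simulateMultitissuePanel(0, ld, seed = 1), "nTissues")
})

test_that("threshold genotype model remains available and reproducible", {
  ld <- simulateLDMatrix(6, 0.7, 6)
  sc <- simScenario("exposure_only", causalSnpExposure = 2L,
                    nExposure = 500L, nCase = 100L, nControl = 100L)
  p1 <- simulateStudyPair(sc, ld, seed = 9, genotypeModel = "threshold",
                          emitGenotypes = TRUE)
  p2 <- simulateStudyPair(sc, ld, seed = 9, genotypeModel = "threshold")
  expect_equal(records(p1$exposure), records(p2$exposure))
  expect_true(all(p1$genotypes$exposure %in% 0:2))
})
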