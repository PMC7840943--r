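test_that("region extraction is a closed, truncated interval", {
  ss <- mkSumStats(c("a", "b", "c"), rep(0.1, 3), rep(0.05, 3),
                   pos = c(100000, 600000, 1100001))
  reg <- extractRegion(ss, "b", 5e5)
  expect_equal(reg@start, 100000)
  expect_equal(reg@end, 1100000)
  expect_setequal(snpIds(reg), c("a", "b"))  # start boundary SNP retained
  reg2 <- extractRegion(mkSumStats("x", 0.1, 0.05, pos = 200000), "x", 5e5)
  expect_equal(reg2@start, 1)
  expect_equal(reg2@end, 700000)
  expect_error(extractRegion(ss, "nope"), "absent")
})

test_that("conditioning on an empty or orthogonal set leaves marginals intact", {
  ss <- mkSumStats(c("a", "b", "c"), c(0.5, 0.2, 0.1),
                   c(0.05, 0.05, 0.05), n = 2000)
  ld <- ldMatrix(c("a", "b", "c"), diag(3))
  reg <- extractRegion(ss, "a", 5e5)
  c0 <- conditionalSumStats(reg, ld, character())
  expect_equal(c0@betaCond, records(ss)$beta)
  expect_equal(c0@seCond, records(ss)$se)
  cOrth <- conditionalSumStats(reg, ld, "c")
  expect_equal(cOrth@betaCond[1:2], records(ss)$beta[1:2], tolerance = 1e-9)
  # self-conditioning annihilates
  expect_equal(cOrth@betaCond[3], 0)
  expect_equal(cOrth@pCond[3], 1)
})

test_that("a collinear condition set raises an error naming the pair", {
  ss <- mkSumStats(c("a", "b", "c"), c(0.5, 0.49, 0.1), rep(0.05, 3),
                   n = 2000)
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.999
  ld <- ldMatrix(c("a", "b", "c"), R)
  reg <- extractRegion(ss, "a", 5e5)
  expect_error(conditionalSumStats(reg, ld, c("a", "b")), "collinear.*a.*b")
})

test_that("conditional estimates match exact least squares on genotypes", {
  ld <- simulateLDMatrix(50, 0.8, 25)
  sc <- simScenario("shared_variant", causalSnpExposure = 12L,
                    nExposure = 2000L)
  p <- simulateStudyPair(sc, ld, seed = 31, emitGenotypes = TRUE)
  G <- p$genotypes$exposure
  y <- p$genotypes$exposurePhenotype
  panel <- ldMatrix(snpIds(ld), cor(G))
  reg <- extractRegion(p$exposure, snpIds(ld)[25])
  S <- c(12, 30)
  cr <- conditionalSumStats(reg, panel, snpIds(ld)[S],
                            varG = apply(G, 2, var))
  others <- setdiff(seq_len(50), S)
  ols <- vapply(others, function(j)
    unname(coef(lm(y ~ G[, j] + G[, S]))[2]), numeric(1))
  expect_lt(max(abs(ols - cr@betaCond[others])), 0.02)
  # conditional SEs are close to the joint-model OLS SEs
  seOls <- vapply(others[1:8], function(j)
    summary(lm(y ~ G[, j] + G[, S]))$coefficients[2, 2], numeric(1))
  expect_equal(cr@seCond[others[1:8]], seOls, tolerance = 0.1)
})

test_that("conditional chi-square does not exceed marginal on concordant signals", {
  # two positively correlated SNPs with concordant effects: conditioning on
  # the stronger one must shrink the other's association
  ld <- simulateLDMatrix(50, 0.8, 25)
  sc <- simScenario("shared_variant", causalSnpExposure = 12L,
                    nExposure = 2000L)
  p <- simulateStudyPair(sc, ld, seed = 32, emitGenotypes = TRUE)
  panel <- ldMatrix(snpIds(ld), cor(p$genotypes$exposure))
  reg <- extractRegion(p$exposure, snpIds(ld)[12])
  cr <- conditionalSumStats(reg, panel, snpIds(ld)[12],
                            varG = apply(p$genotypes$exposure, 2, var))
  rec <- records(p$exposure)
  for (j in c(10, 11, 13, 14)) {
    chiM <- (rec$beta[j] / rec$se[j])^2
    chiC <- (cr@betaCond[j] / cr@seCond[j])^2
    expect_lte(chiC, chiM + 1e-6)
  }
})

test_that("stepwise selection finds the true number of signals", {
  ld <- simulateLDMatrix(40, 0.8, 20)
  ids <- snpIds(ld)
  cholR <- chol(ldr(ld) + diag(1e-10, 40))
  oneHit <- twoHit <- integer(60)
  oneTag <- logical(60)
  for (i in 1:60) {
    set.seed(7000 + i)
    n <- 3000
    mafs <- runif(40, 0.1, 0.5)
    Z <- matrix(rnorm(n * 40), n) %*% cholR
    G <- sweep(sweep(Z, 2, sqrt(2 * mafs * (1 - mafs)), "*"), 2,
               2 * mafs, "+")
    panel <- ldMatrix(ids, cor(G))
    vG <- apply(G, 2, var)
    mk <- function(y) {
      st <- oracleMarginal(G, y)
      mkSumStats(ids, st$beta, st$se, pval = st$pval, n = n,
                 eaf = colMeans(G) / 2)
    }
    # single causal SNP
    y1 <- 0.4 * scale(G[, 10], scale = FALSE) + rnorm(n)
    sel1 <- stepwiseSelect(extractRegion(mk(y1), ids[20]), panel,
                           varG = vG)
    oneHit[i] <- length(sel1)
    oneTag[i] <- length(sel1) >= 1 &&
      max(ldr(panel)[match(sel1, ids), 10]^2) >= 0.8
    # two uncorrelated causal SNPs (different blocks, r = 0)
    y2 <- 0.35 * scale(G[, 10], scale = FALSE) +
      0.35 * scale(G[, 30], scale = FALSE) + rnorm(n)
    sel2 <- stepwiseSelect(extractRegion(mk(y2), ids[20]), panel,
                           varG = vG)
    twoHit[i] <- length(sel2)
  }
  expect_gte(mean(oneHit == 1), 0.95)
  expect_gte(mean(oneTag), 0.95)
  expect_gte(mean(twoHit == 2), 0.90)
  # null region selects nothing
  set.seed(1)
  stN <- oracleMarginal(matrix(rnorm(500 * 40), 500) %*% cholR, rnorm(500))
  nullSS <- mkSumStats(ids, stN$beta, stN$se, pval = stN$pval, n = 500)
  expect_length(stepwiseSelect(extractRegion(nullSS, ids[20]), ld), 0)
})
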