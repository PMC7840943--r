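gene <- geneAnnotation("GENE1", "1", tss = 2e6)

test_that("cis filtering uses a closed 1 Mbp interval around the TSS", {
  ss <- mkSumStats(c("in1", "edge", "out", "trans"),
                   beta = rep(0.5, 4), se = rep(0.05, 4),
                   pos = c(2e6, 3e6, 3e6 + 1, 2e6),
                   chrom = c("1", "1", "1", "2"))
  kept <- records(cisFilter(ss, gene, 1e6))$snp
  expect_setequal(kept, c("in1", "edge"))  # tss+1e6 retained, +1 excluded
})

test_that("greedy clumping keeps the best of correlated pairs", {
  ss <- mkSumStats(c("a", "b"), c(0.5, 0.4), c(0.05, 0.05),
                   pval = c(1e-12, 1e-9))
  ld <- ldMatrix(c("a", "b"), matrix(c(1, 1, 1, 1), 2))
  expect_identical(clumpSnps(ss, ld, 5e-8, 0.01), "a")
  ld0 <- ldMatrix(c("a", "b"), diag(2))
  expect_setequal(clumpSnps(ss, ld0, 5e-8, 0.01), c("a", "b"))
  expect_error(clumpSnps(ss, ldMatrix("a", matrix(1)), 5e-8), "missing")
})

test_that("clumping matches an exhaustive pairwise checker on random instances", {
  for (s in 1:12) {
    set.seed(s)
    k <- 12
    ids <- sprintf("s%02d", 1:k)
    # random PSD correlation matrix
    A <- matrix(rnorm(k * k), k)
    R <- cov2cor(crossprod(A) + diag(k) * 0.5)
    ld <- ldMatrix(ids, R)
    ss <- mkSumStats(ids, rnorm(k), runif(k, 0.02, 0.1),
                     pval = 10^-runif(k, 0, 12))
    thr <- 0.3
    kept <- clumpSnps(ss, ld, p = 0.05, r2Threshold = thr)
    rec <- records(ss)
    r2 <- R^2; dimnames(r2) <- list(ids, ids)
    # every kept pair is below the threshold
    if (length(kept) > 1) {
      pairs <- combn(kept, 2)
      expect_true(all(r2[t(pairs)] < thr))
    }
    # every dropped candidate conflicts with a better-P kept SNP
    cand <- rec$snp[rec$pval < 0.05]
    for (d in setdiff(cand, kept)) {
      better <- kept[rec$pval[match(kept, rec$snp)] <=
                       rec$pval[match(d, rec$snp)]]
      expect_true(any(r2[d, better] >= thr))
    }
  }
})

test_that("clumping is invariant under input row order", {
  set.seed(99)
  k <- 10
  ids <- sprintf("r%02d", 1:k)
  R <- cov2cor(crossprod(matrix(rnorm(k * k), k)) + diag(k))
  ld <- ldMatrix(ids, R)
  pv <- 10^-runif(k, 0, 10)
  pv[2] <- pv[1]  # force a tie broken by position
  ss <- mkSumStats(ids, rnorm(k), runif(k, 0.02, 0.1), pval = pv)
  perm <- sample(k)
  rec <- records(ss)[perm, ]
  ssP <- sumStats("trait", "quantitative", rec)
  expect_identical(clumpSnps(ss, ld, 0.05, 0.3),
                   clumpSnps(ssP, ld, 0.05, 0.3))
})

test_that("adding an uncorrelated significant SNP grows the instrument by one", {
  ids <- c("a", "b", "c")
  ld <- ldMatrix(ids, diag(3))
  ss2 <- mkSumStats(ids[1:2], c(0.5, 0.4), c(0.05, 0.05),
                    pval = c(1e-10, 1e-9))
  ss3 <- mkSumStats(ids, c(0.5, 0.4, 0.3), c(0.05, 0.05, 0.05),
                    pval = c(1e-10, 1e-9, 1e-12))
  expect_equal(length(clumpSnps(ss3, ld, 5e-8, 0.01)),
               length(clumpSnps(ss2, ldMatrix(ids[1:2], diag(2)),
                                5e-8, 0.01)) + 1L)
})

test_that("instrument selection honours mode thresholds and cis restriction", {
  ids <- c("cisStrong", "cisWeak", "transStrong")
  ss <- mkSumStats(ids, c(0.5, 0.3, 0.9), c(0.05, 0.06, 0.05),
                   pval = c(1e-10, 1e-5, 1e-30),
                   pos = c(2e6, 2.1e6, 2e6),
                   chrom = c("1", "1", "7"))
  ld <- ldMatrix(ids, diag(3))
  disc <- selectInstruments(ss, gene, ld, "discovery")
  expect_identical(snpIds(disc), "cisStrong")
  tis <- selectInstruments(ss, gene, ld, "tissue_specific")
  expect_setequal(snpIds(tis), c("cisStrong", "cisWeak"))
  expect_false("transStrong" %in% snpIds(tis))  # trans never instrumented
  none <- selectInstruments(mkSumStats("x", 0.1, 0.1, pval = 0.5,
                                       pos = 2e6),
                            gene, ldMatrix("x", matrix(1)), "discovery")
  expect_equal(nrow(records(none)), 0L)
})
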