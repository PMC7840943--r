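# Small in-code fixtures shared across test files.

# Quick SumStats builder: sensible defaults, override any column.
mkSumStats <- function(snp, beta, se, pval = NULL, pos = NULL,
                       chrom = "1", ea = "A", oa = "G", eaf = 0.3,
                       n = 1000, nCase = 0, nControl = 0,
                       traitId = "trait", traitType = "quantitative") {
  k <- length(snp)
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-320)
  if (is.null(pos)) pos <- seq(1000, by = 1000, length.out = k)
  sumStats(traitId, traitType,
           data.frame(snp = snp, chrom = chrom, pos = pos,
                      ea = rep_len(ea, k), oa = rep_len(oa, k),
                      eaf = rep_len(eaf, k), beta = beta, se = se,
                      pval = pval, n = rep_len(n, k),
                      nCase = rep_len(nCase, k),
                      nControl = rep_len(nControl, k),
                      stringsAsFactors = FALSE))
}

# Marginal per-SNP OLS computed independently of the package internals
# (used as an oracle when tests build phenotypes from emitted genotypes).
oracleMarginal <- function(G, y) {
  y <- as.numeric(y)
  n <- length(y)
  gc <- sweep(G, 2, colMeans(G))
  yc <- y - mean(y)
  gg <- colSums(gc^2)
  beta <- colSums(gc * yc) / gg
  se <- sqrt(pmax(sum(yc^2) - beta^2 * gg, 0) / (n - 2) / gg)
  list(beta = beta, se = se, pval = 2 * pnorm(-abs(beta / se)))
}

# Shared-variant replicate statistics at the calibration sample sizes,
# computed once per test run and reused by the MR-recovery and Steiger
# acceptance blocks (identical study conditions).
.sharedRepCache <- new.env(parent = emptyenv())
sharedVariantReps <- function(nrep = 200) {
  key <- as.character(nrep)
  if (!is.null(.sharedRepCache[[key]])) return(.sharedRepCache[[key]])
  ld <- simulateLDMatrix(20, 0.8, 20)
  sc <- simScenario("shared_variant", causalSnpExposure = 10L)
  wald <- numeric(nrep)
  steigerTrue <- logical(nrep)
  for (i in seq_len(nrep)) {
    p <- simulateStudyPair(sc, ld, seed = 20000 + i)
    ex <- records(p$exposure)
    ou <- records(p$outcome)
    wald[i] <- ou$beta[10] / ex$beta[10]
    ins <- new("Instrument", geneId = "g", tissue = "brain",
               records = ex[10, , drop = FALSE], clumpR2 = 0.01,
               pThreshold = 5e-8)
    steigerTrue[i] <- steigerForInstrument(ins, p$outcome)@category == "true"
  }
  .sharedRepCache[[key]] <- list(wald = wald, steigerTrue = steigerTrue)
  .sharedRepCache[[key]]
}
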