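#' @include sumstats-io.R
NULL

#' Simulate a block-diagonal AR(1) LD matrix
#'
#' Entries inside a block follow \code{r[j,k] = rho^|j-k|}; entries between
#' blocks are 0.  Such matrices are symmetric, unit-diagonal and positive
#' semi-definite by construction.
#'
#' @param nSnps number of SNPs.
#' @param rho within-block AR(1) correlation, in [0, 1).
#' @param blockSize SNPs per block (last block may be shorter);
#'   \code{blockSize <= nSnps}.
#' @param seed unused (the matrix is deterministic); accepted so all
#'   generator entry points share one signature.
#' @param snpPrefix prefix for the generated SNP identifiers.
#' @return an \linkS4class{LDMatrix}.
#' @examples
#' simulateLDMatrix(5, 0.0, 5)        # identity
#' ldr(simulateLDMatrix(4, 0.8, 4))[1, 3]  # 0.8^2
#' @export
simulateLDMatrix <- function(nSnps, rho, blockSize, seed = NULL,
                             snpPrefix = "rs") {
  if (nSnps < 1 || blockSize < 1 || blockSize > nSnps)
    .stopf("need 1 <= blockSize <= nSnps")
  if (!is.finite(rho) || rho < 0 || rho >= 1)
    .stopf("rho must lie in [0, 1)")
  r <- matrix(0, nSnps, nSnps)
  starts <- seq(1L, nSnps, by = blockSize)
  for (s in starts) {
    e <- min(s + blockSize - 1L, nSnps)
    idx <- s:e
    r[idx, idx] <- rho^abs(outer(idx, idx, "-"))
  }
  ldMatrix(sprintf("%s%04d", snpPrefix, seq_len(nSnps)), r)
}

#' Define a simulation scenario
#'
#' The five scenarios mirror the five colocalisation hypotheses: \code{null}
#' (no signal, H0), \code{exposure_only} (H1), \code{outcome_only} (H2),
#' \code{distinct_variants} (two causal variants in LD, H3) and
#' \code{shared_variant} (one shared causal variant with a causal
#' exposure-to-outcome effect, H4).
#'
#' Defaults are the calibration conditions used throughout: an eQTL explaining
#' \code{betaGx = 0.5} SD expression per allele, a causal effect \code{theta =
#' 0.4} log-odds per SD expression, 5000 exposure individuals and 5000 cases /
#' 5000 controls, MAFs uniform on [0.1, 0.5].
#'
#' @param name scenario name (see Description).
#' @param causalSnpExposure,causalSnpOutcome 1-based SNP indices (NA when the
#'   scenario has no such variant).
#' @param betaGx per-allele effect on expression (SD units).
#' @param betaGy per-allele log-odds effect of the outcome's own causal SNP
#'   (used by outcome_only / distinct_variants).
#' @param theta causal log-odds effect per SD expression (shared_variant only).
#' @param nExposure,nCase,nControl sample sizes.
#' @param mafRange MAF sampling range within (0, 0.5].
#' @return a validated \linkS4class{SimScenario}.
#' @export
simScenario <- function(name, causalSnpExposure = NA_integer_,
                        causalSnpOutcome = NA_integer_, betaGx = 0.5,
                        betaGy = 0.3, theta = 0.4, nExposure = 5000L,
                        nCase = 5000L, nControl = 5000L,
                        mafRange = c(0.1, 0.5)) {
  new("SimScenario", name = name,
      causalSnpExposure = as.integer(causalSnpExposure),
      causalSnpOutcome = as.integer(causalSnpOutcome),
      betaGx = betaGx, betaGy = betaGy, theta = theta,
      nExposure = as.integer(nExposure), nCase = as.integer(nCase),
      nControl = as.integer(nControl), mafRange = mafRange)
}

## Draw an n x m genotype matrix consistent with the target LD.
##  - "dosage": G = 2p + sqrt(2p(1-p)) * Z, Z ~ MVN(0, R); realized LD equals
##    the target exactly and Var(G_j) = 2p_j(1-p_j), as for imputed dosages.
##  - "threshold": two haplotypes, each an indicator of a correlated standard
##    normal falling below qnorm(maf); realized LD is attenuated relative to
##    the target (documented in the methods vignette).
.simGenotypes <- function(n, mafs, cholR, model) {
  m <- length(mafs)
  if (model == "dosage") {
    Z <- matrix(stats::rnorm(n * m), n, m) %*% cholR
    G <- sweep(sweep(Z, 2, sqrt(2 * mafs * (1 - mafs)), "*"),
               2, 2 * mafs, "+")
  } else {
    t1 <- matrix(stats::rnorm(n * m), n, m) %*% cholR
    t2 <- matrix(stats::rnorm(n * m), n, m) %*% cholR
    thr <- matrix(stats::qnorm(mafs), n, m, byrow = TRUE)
    G <- (t1 < thr) + (t2 < thr)
    storage.mode(G) <- "double"
  }
  G
}

## Marginal per-SNP linear regression (vectorised): beta, se, p.
.marginalQuant <- function(G, y) {
  n <- length(y)
  gc <- sweep(G, 2, colMeans(G))
  yc <- y - mean(y)
  gg <- colSums(gc^2)
  beta <- colSums(gc * yc) / gg
  rss <- sum(yc^2) - beta^2 * gg
  rss[rss < 0] <- 0
  se <- sqrt(rss / (n - 2) / gg)
  list(beta = beta, se = se, pval = .pFromZ(beta / se))
}

## Case-control marginal statistics by the logistic score approximation:
## z from the per-SNP linear regression of case status on dosage, SE from
## 1/sqrt(n * s(1-s) * 2p(1-p)), beta = z * SE (log-odds scale).
.marginalBinary <- function(G, y, eaf) {
  n <- length(y)
  s <- mean(y)
  lin <- .marginalQuant(G, y)
  z <- lin$beta / lin$se
  se <- 1 / sqrt(n * s * (1 - s) * 2 * eaf * (1 - eaf))
  list(beta = z * se, se = se, pval = .pFromZ(z))
}

.buildRecords <- function(ids, chrom, pos, eaf, stats, n, nCase = 0L,
                          nControl = 0L) {
  data.frame(snp = ids, chrom = chrom, pos = pos, ea = "A", oa = "G",
             eaf = pmin(pmax(eaf, 1e-4), 1 - 1e-4), beta = stats$beta,
             se = stats$se, pval = pmax(stats$pval, 1e-320), n = n,
             nCase = nCase, nControl = nControl, stringsAsFactors = FALSE)
}

#' Simulate a linked exposure/outcome study pair with known causal truth
#'
#' Generates marginal cis-eQTL summary statistics (quantitative exposure) and
#' a case-control outcome GWAS over a shared SNP region, from two independent
#' individual-level samples consistent with the supplied LD matrix.  The
#' exposure is \code{betaGx * G_causal + noise}, scaled to unit total
#' variance.  The outcome liability is \code{theta} times the (independently
#' re-sampled) exposure plus, under \code{outcome_only}/
#' \code{distinct_variants}, a direct \code{betaGy} per-allele effect of the
#' outcome's own causal SNP, plus standard logistic noise; case status is
#' assigned by top-fraction thresholding at the case fraction
#' \code{nCase/(nCase+nControl)}.  With logistic liability noise the per-SNP
#' log-odds slope at the causal SNP is \code{theta * betaGx}, so the Wald
#' ratio targets \code{theta} directly.
#'
#' Per-SNP effects are computed by marginal linear regression (exposure) and
#' by the logistic score approximation (outcome): \code{beta = z * SE} with
#' \code{SE = 1/sqrt(n * s(1-s) * 2p(1-p))}.  Monomorphic draws (possible only
#' under the threshold genotype model at small n) are regenerated with a
#' message, at most 100 times.  Fully reproducible from \code{seed}.
#'
#' @param scenario a \linkS4class{SimScenario}.
#' @param ld an \linkS4class{LDMatrix}; causal SNP indices must lie within it.
#' @param seed integer seed.
#' @param emitGenotypes also return the genotype matrices (for oracle tests).
#' @param genotypeModel \code{"dosage"} (default; realized LD matches the
#'   target exactly) or \code{"threshold"} (two thresholded Gaussian
#'   haplotypes; attenuated LD).
#' @param chrom,posStart,posStep genomic coordinates assigned to the SNPs.
#' @return list with \code{exposure} and \code{outcome}
#'   (\linkS4class{SumStats}), \code{truth} (\linkS4class{SimTruth}), and when
#'   \code{emitGenotypes} is set, \code{genotypes} (list with
#'   \code{exposure}, \code{outcome} matrices, \code{exposurePhenotype} and
#'   \code{caseStatus}).
#' @export
simulateStudyPair <- function(scenario, ld, seed, emitGenotypes = FALSE,
                              genotypeModel = c("dosage", "threshold"),
                              chrom = "1", posStart = 1e6, posStep = 1000) {
  stopifnot(is(scenario, "SimScenario"), is(ld, "LDMatrix"))
  genotypeModel <- match.arg(genotypeModel)
  m <- length(ld@snpIds)
  cx <- scenario@causalSnpExposure
  cy <- scenario@causalSnpOutcome
  if ((!is.na(cx) && (cx < 1 || cx > m)) ||
      (!is.na(cy) && (cy < 1 || cy > m)))
    .stopf("causal SNP index outside the LD matrix dimension (%d)", m)
  nx <- scenario@nExposure
  ny <- scenario@nCase + scenario@nControl
  if (nx < 4L || ny < 4L) .stopf("sample sizes too small to fit")
  caseFrac <- scenario@nCase / ny
  set.seed(seed)
  cholR <- chol(ld@r + diag(1e-10, m))

  for (try in seq_len(100L)) {
    mafs <- stats::runif(m, scenario@mafRange[1], scenario@mafRange[2])
    Gx <- .simGenotypes(nx, mafs, cholR, genotypeModel)
    Gy <- .simGenotypes(ny, mafs, cholR, genotypeModel)
    vx <- apply(Gx, 2, stats::var)
    vy <- apply(Gy, 2, stats::var)
    if (all(vx > 0) && all(vy > 0)) break
    if (try == 100L) .stopf("monomorphic SNPs after 100 redraws")
    message("monomorphic SNP drawn; regenerating (attempt ", try, ")")
  }

  exposureComponent <- function(G) {
    if (is.na(cx) || scenario@name %in% c("null", "outcome_only"))
      return(stats::rnorm(nrow(G)))
    g <- G[, cx] - mean(G[, cx])
    varG <- stats::var(G[, cx])
    noiseVar <- 1 - scenario@betaGx^2 * varG
    if (noiseVar <= 0)
      .stopf("betaGx too large for unit-variance expression")
    scenario@betaGx * g + stats::rnorm(nrow(G), sd = sqrt(noiseVar))
  }

  ## exposure study
  yx <- exposureComponent(Gx)
  statX <- .marginalQuant(Gx, yx)

  ## outcome study: liability with standard logistic noise, thresholded
  liab <- stats::rlogis(ny)
  if (scenario@name == "shared_variant")
    liab <- liab + scenario@theta * exposureComponent(Gy)
  if (scenario@name %in% c("outcome_only", "distinct_variants"))
    liab <- liab + scenario@betaGy * (Gy[, cy] - mean(Gy[, cy]))
  cut <- stats::quantile(liab, 1 - caseFrac, names = FALSE)
  yBin <- as.numeric(liab > cut)
  eafY <- colMeans(Gy) / 2
  statY <- .marginalBinary(Gy, yBin, pmin(pmax(eafY, 1e-4), 1 - 1e-4))

  pos <- posStart + (seq_len(m) - 1L) * posStep
  exposure <- sumStats("gene:sim", "quantitative",
                       .buildRecords(ld@snpIds, chrom, pos, colMeans(Gx) / 2,
                                     statX, nx),
                       metadata = list(seed = seed, scenario = scenario@name))
  outcome <- sumStats("outcome:sim", "binary",
                      .buildRecords(ld@snpIds, chrom, pos, eafY, statY, ny,
                                    scenario@nCase, scenario@nControl),
                      metadata = list(seed = seed, scenario = scenario@name))
  truth <- new("SimTruth", scenario = scenario,
               trueWaldEffect = if (scenario@name == "shared_variant")
                 scenario@theta else 0,
               seed = as.integer(seed))
  out <- list(exposure = exposure, outcome = outcome, truth = truth)
  if (emitGenotypes)
    out$genotypes <- list(exposure = Gx, outcome = Gy,
                          exposurePhenotype = yx, caseStatus = yBin)
  out
}

#' Simulate a multi-tissue cis-eQTL panel
#'
#' Generates per-tissue exposure summary statistics over a shared SNP region,
#' emulating tissue-level eQTL panels of modest size (defaults span the
#' 114-209 range typical of single-tissue brain panels), plus a per-tissue
#' mean-expression vector for tissue-specificity (tau) testing.
#'
#' When \code{sharedExposureEffect} is TRUE all tissues share the same causal
#' effect \code{betaGx} (the heterogeneity null); otherwise \code{betaGx} may
#' be a per-tissue vector, including sign flips.
#'
#' @param nTissues number of tissues (1-13).
#' @param ld an \linkS4class{LDMatrix}.
#' @param seed integer seed.
#' @param causalSnp shared causal SNP index.
#' @param betaGx scalar (shared) or per-tissue vector of causal effects.
#' @param sharedExposureEffect force a common effect across tissues.
#' @param nRange range from which per-tissue sample sizes are drawn.
#' @param expression optional per-tissue mean-expression vector; by default
#'   drawn log-normal (meanlog 1, sdlog 1).
#' @param genotypeModel passed to the genotype generator.
#' @return list with \code{sumstats} (named list of per-tissue
#'   \linkS4class{SumStats}), \code{expression} (named numeric vector),
#'   \code{tissues}, \code{betaGx} (per-tissue effects used) and \code{n}
#'   (per-tissue sample sizes).
#' @export
simulateMultitissuePanel <- function(nTissues, ld, seed, causalSnp = 1L,
                                     betaGx = 0.5,
                                     sharedExposureEffect = TRUE,
                                     nRange = c(114L, 209L),
                                     expression = NULL,
                                     genotypeModel = c("dosage",
                                                       "threshold")) {
  stopifnot(is(ld, "LDMatrix"))
  genotypeModel <- match.arg(genotypeModel)
  if (nTissues < 1L || nTissues > 13L)
    .stopf("nTissues must lie in 1..13")
  m <- length(ld@snpIds)
  if (causalSnp < 1L || causalSnp > m)
    .stopf("causal SNP index outside the LD matrix dimension (%d)", m)
  if (sharedExposureEffect) {
    betas <- rep(betaGx[1], nTissues)
  } else {
    betas <- rep_len(betaGx, nTissues)
  }
  tissues <- sprintf("tissue%02d", seq_len(nTissues))
  set.seed(seed)
  cholR <- chol(ld@r + diag(1e-10, m))
  ns <- as.integer(round(stats::runif(nTissues, nRange[1], nRange[2])))
  if (is.null(expression)) expression <- stats::rlnorm(nTissues, 1, 1)
  names(expression) <- tissues
  pos <- 1e6 + (seq_len(m) - 1L) * 1000
  out <- vector("list", nTissues)
  for (t in seq_len(nTissues)) {
    mafs <- stats::runif(m, 0.1, 0.5)
    G <- .simGenotypes(ns[t], mafs, cholR, genotypeModel)
    g <- G[, causalSnp] - mean(G[, causalSnp])
    varG <- stats::var(G[, causalSnp])
    noiseVar <- 1 - betas[t]^2 * varG
    if (noiseVar <= 0) .stopf("betaGx too large for unit-variance expression")
    y <- betas[t] * g + stats::rnorm(ns[t], sd = sqrt(noiseVar))
    st <- .marginalQuant(G, y)
    out[[t]] <- sumStats(paste0("gene:", tissues[t]), "quantitative",
                         .buildRecords(ld@snpIds, "1", pos, colMeans(G) / 2,
                                       st, ns[t]),
                         metadata = list(seed = seed, tissue = tissues[t]))
  }
  names(out) <- tissues
  list(sumstats = out, expression = expression, tissues = tissues,
       betaGx = betas, n = ns)
}

#' Write a simulated study pair and its truth sidecar to TSV
#'
#' @param pair result of \code{\link{simulateStudyPair}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the files written.
#' @export
writeStudyPair <- function(pair, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- file.path(dir, paste0(prefix, "_exposure.tsv"))
  fy <- file.path(dir, paste0(prefix, "_outcome.tsv"))
  ft <- file.path(dir, paste0(prefix, "_truth.tsv"))
  writeSumStats(pair$exposure, fx)
  writeSumStats(pair$outcome, fy)
  sc <- pair$truth@scenario
  .writeTsv(data.frame(SCENARIO = sc@name,
                       CAUSAL_SNP_EXPOSURE = sc@causalSnpExposure,
                       CAUSAL_SNP_OUTCOME = sc@causalSnpOutcome,
                       BETA_GX = sc@betaGx, BETA_GY = sc@betaGy,
                       THETA = sc@theta,
                       TRUE_WALD_EFFECT = pair$truth@trueWaldEffect,
                       SEED = pair$truth@seed), ft)
  c(exposure = fx, outcome = fy, truth = ft)
}
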