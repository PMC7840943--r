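#' @include sumstats-io.R
NULL

#' Extract the region around a lead SNP
#'
#' Closed 1-based interval \code{[pos - halfWindowBp, pos + halfWindowBp]}
#' on the lead SNP's chromosome, truncated at 1.
#'
#' @param sumstats a \linkS4class{SumStats} containing the lead SNP.
#' @param lead lead SNP id.
#' @param halfWindowBp half-window in bp (default 500 kbp).
#' @return a \linkS4class{Region}.
#' @export
extractRegion <- function(sumstats, lead, halfWindowBp = 5e5) {
  stopifnot(is(sumstats, "SumStats"))
  rec <- sumstats@records
  i <- match(lead, rec$snp)
  if (is.na(i)) .stopf("lead SNP '%s' absent from %s", lead,
                       sumstats@traitId)
  chrom <- rec$chrom[i]
  start <- max(1, rec$pos[i] - halfWindowBp)
  end <- rec$pos[i] + halfWindowBp
  keep <- rec$chrom == chrom & rec$pos >= start & rec$pos <= end
  new("Region",
      sumstats = sumStats(sumstats@traitId, sumstats@traitType,
                          rec[keep, , drop = FALSE], sumstats@metadata),
      chrom = chrom, start = start, end = end, leadSnp = lead)
}

## Approximate genotype cross-products from summary statistics + LD reference:
##   X'X[j,k] = n * sqrt(d_j d_k) * r_jk,  d_j = 2 eaf_j (1 - eaf_j)
##   X'y[j]   = n * d_j * beta_j
.crossProducts <- function(beta, eaf, n, r, varG = NULL) {
  d <- if (is.null(varG)) 2 * eaf * (1 - eaf) else varG
  sd <- sqrt(d)
  XtX <- n * (sd %o% sd) * r
  Xty <- n * d * beta
  list(XtX = XtX, Xty = Xty, d = d)
}

#' Approximate conditional association analysis from summary statistics
#'
#' Conditions every SNP in a region on a set of index SNPs using only
#' marginal statistics and an LD reference, in the style of conditional/joint
#' analysis from GWAS summary data.  Genotype cross-products are approximated
#' as \code{X'X[j,k] = n sqrt(d_j d_k) r_jk} with \code{d_j = 2 eaf_j (1 -
#' eaf_j)} and \code{X'y_j = n d_j beta_j}; joint effects of the condition
#' set come from the normal equations, and the conditional per-allele effect
#' of a remaining SNP j is the joint-model least-squares coefficient
#' \code{(X_j'y - X_j'X_S (X_S'X_S)^{-1} X_S'y) / (X_j'X_j - X_j'X_S
#' (X_S'X_S)^{-1} X_S'X_j)}, i.e. the residualised numerator over the Schur
#' complement, which reproduces exact multivariable least squares when the
#' cross-products are exact.  Conditional SEs use the conditional residual
#' variance with the
#' phenotypic variance estimated from the region's own summary statistics.
#' SNPs in the condition set are reported with zero conditional effect
#' (self-conditioning annihilates).
#'
#' @param region a \linkS4class{Region}.
#' @param ld an \linkS4class{LDMatrix} covering the region.
#' @param conditionSet SNP ids to condition on (subset of the region; may be
#'   empty, in which case marginal statistics are returned unchanged).
#' @param n sample size (defaults to the region's per-record \code{n}; for
#'   binary traits pass the effective sample size).
#' @param eafs optional per-SNP effect-allele frequencies (defaults to the
#'   region records).
#' @param varG optional per-SNP genotype variances from the LD reference
#'   panel; when supplied they replace the Hardy-Weinberg approximation
#'   \code{2 eaf (1 - eaf)} and sharpen the cross-product reconstruction.
#' @param collinearR2 condition-set collinearity guard (default r2 > 0.99
#'   errors, naming the offending pair).
#' @return a \linkS4class{ConditionalRegion}.
#' @export
conditionalSumStats <- function(region, ld, conditionSet, n = NULL,
                                eafs = NULL, varG = NULL,
                                collinearR2 = 0.99) {
  stopifnot(is(region, "Region"), is(ld, "LDMatrix"))
  rec <- region@sumstats@records
  ids <- rec$snp
  bad <- setdiff(conditionSet, ids)
  if (length(bad))
    .stopf("condition set SNP(s) outside the region: %s",
           paste(bad, collapse = ", "))
  sub <- subsetLDMatrix(ld, ids)
  r <- sub@r
  if (is.null(n)) n <- stats::median(rec$n)
  if (is.null(eafs)) eafs <- rec$eaf
  m <- length(ids)

  if (length(conditionSet) == 0L) {
    return(new("ConditionalRegion", base = region,
               conditionedOn = character(), betaCond = rec$beta,
               seCond = rec$se, pCond = rec$pval))
  }

  S <- match(conditionSet, ids)
  ## collinearity guard within the condition set
  if (length(S) > 1L) {
    r2S <- r[S, S, drop = FALSE]^2
    diag(r2S) <- 0
    if (any(r2S > collinearR2)) {
      w <- sort(which(r2S == max(r2S), arr.ind = TRUE)[1, ])
      .stopf("collinear condition set: %s and %s (r2 = %.3f)",
             conditionSet[w[1]], conditionSet[w[2]], max(r2S))
    }
  }

  cp <- .crossProducts(rec$beta, eafs, n, r, varG)
  XtX <- cp$XtX; Xty <- cp$Xty
  XSS <- XtX[S, S, drop = FALSE]
  bS <- solve(XSS, Xty[S])

  ## phenotypic sum of squares from the region's own marginal statistics:
  ## se_j^2 = (var_y / d_j - beta_j^2) / (n - 2)  =>  var_y estimate per SNP
  varY <- stats::median(cp$d * (rec$se^2 * (n - 2) + rec$beta^2))
  yty <- n * varY

  betaCond <- rec$beta
  seCond <- rec$se
  others <- setdiff(seq_len(m), S)
  dfRes <- max(n - length(S) - 2, 1)
  for (j in others) {
    XjS <- XtX[j, S, drop = FALSE]
    numer <- Xty[j] - drop(XjS %*% bS)
    Dcond <- XtX[j, j] - drop(XjS %*% solve(XSS, t(XjS)))
    if (Dcond <= 1e-8 * XtX[j, j]) {
      ## SNP effectively collinear with the condition set
      betaCond[j] <- 0
      seCond[j] <- Inf
      next
    }
    betaCond[j] <- numer / Dcond
    rss <- yty - sum(bS * Xty[S]) - betaCond[j] * numer
    sigma2 <- max(rss, 1e-12) / dfRes
    seCond[j] <- sqrt(sigma2 / Dcond)
  }
  betaCond[S] <- 0
  seCond[S] <- NA_real_
  pCond <- ifelse(is.na(seCond) | !is.finite(seCond), 1,
                  .pFromZ(betaCond / seCond))
  new("ConditionalRegion", base = region, conditionedOn = conditionSet,
      betaCond = betaCond, seCond = seCond, pCond = pCond)
}

#' Stepwise selection of independent association signals in a region
#'
#' Model selection in the style of summary-statistic joint analysis: starting
#' from the empty model, repeatedly add the SNP with the smallest conditional
#' P value among candidates whose r-squared with every selected SNP is below
#' 0.9, while that P value is below \code{pEntry}.
#'
#' @param region a \linkS4class{Region}.
#' @param ld an \linkS4class{LDMatrix} covering the region.
#' @param pEntry entry threshold (default 5e-8).
#' @param n,eafs,varG passed to \code{\link{conditionalSumStats}}.
#' @param maxSignals safety cap on the number of selected signals.
#' @return character vector of selected SNP ids, in order of entry.
#' @export
stepwiseSelect <- function(region, ld, pEntry = 5e-8, n = NULL, eafs = NULL,
                           varG = NULL, maxSignals = 10L) {
  stopifnot(is(region, "Region"))
  rec <- region@sumstats@records
  if (nrow(rec) == 0L) .stopf("empty region")
  sub <- subsetLDMatrix(ld, rec$snp)
  selected <- character()
  repeat {
    cond <- conditionalSumStats(region, ld, selected, n = n, eafs = eafs,
                                varG = varG)
    p <- cond@pCond
    cand <- setdiff(seq_along(p), match(selected, rec$snp))
    if (length(selected)) {
      r2max <- apply(sub@r[cand, match(selected, rec$snp),
                           drop = FALSE]^2, 1, max)
      cand <- cand[r2max < 0.9]
    }
    if (!length(cand)) break
    best <- cand[which.min(p[cand])]
    if (p[best] >= pEntry) break
    selected <- c(selected, rec$snp[best])
    if (length(selected) >= maxSignals) break
  }
  selected
}

#' Flatten a ConditionalRegion to a TSV-shaped data.frame
#' @param x a \linkS4class{ConditionalRegion}.
#' @return data.frame with marginal and conditional beta/se/p per SNP.
#' @export
conditionalTable <- function(x) {
  rec <- x@base@sumstats@records
  data.frame(SNP = rec$snp, CHR = rec$chrom, POS = rec$pos,
             BETA = rec$beta, SE = rec$se, P = rec$pval,
             BETA_COND = x@betaCond, SE_COND = x@seCond, P_COND = x@pCond,
             CONDITIONED = rec$snp %in% x@conditionedOn,
             stringsAsFactors = FALSE)
}
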