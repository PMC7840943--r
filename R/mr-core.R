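#' @include AllClasses.R utils.R
NULL

#' Wald ratio estimator for a single instrument SNP
#'
#' \code{beta = by/bx}.  The default standard error is the first-order delta
#' approximation \code{sy/|bx|}; the second-order form
#' \code{sqrt(sy^2/bx^2 + by^2 * sx^2 / bx^4)} additionally propagates the
#' exposure-side uncertainty.
#'
#' @param bx,sx exposure effect and SE.
#' @param by,sy outcome effect and SE.
#' @param seMethod \code{"first_order"} (default) or \code{"second_order"}.
#' @return list with \code{beta}, \code{se}.
#' @examples
#' waldRatio(0.5, 0.05, 0.2, 0.05)  # beta 0.4, se 0.1 (first order)
#' @export
waldRatio <- function(bx, sx, by, sy,
                      seMethod = c("first_order", "second_order")) {
  seMethod <- match.arg(seMethod)
  if (!is.finite(bx) || bx == 0)
    .stopf("Wald ratio undefined: exposure effect is zero")
  if (sx <= 0 || sy <= 0) .stopf("standard errors must be > 0")
  beta <- by / bx
  se <- if (seMethod == "first_order") sy / abs(bx)
        else sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  list(beta = beta, se = se)
}

#' Fixed-effect inverse-variance-weighted combination of per-SNP ratios
#'
#' \code{w_i = 1/se_i^2}; \code{beta = sum(w b)/sum(w)};
#' \code{se = 1/sqrt(sum(w))}; two-sided normal P.
#'
#' @param betas per-SNP Wald ratio estimates.
#' @param ses their standard errors.
#' @return list with \code{beta}, \code{se}, \code{pval}.
#' @export
ivw <- function(betas, ses) {
  if (length(betas) == 0L) .stopf("ivw requires at least one ratio")
  if (length(betas) != length(ses)) .stopf("betas and ses lengths differ")
  if (any(ses <= 0)) .stopf("standard errors must be > 0")
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  list(beta = beta, se = se, pval = .pFromZ(beta / se))
}

#' Bonferroni and suggestive multiple-testing thresholds
#'
#' \code{bonferroni = 0.05 / nGenes}; the suggestive threshold relaxes it by
#' the number of tissues, \code{suggestive = bonferroni * nTissues} (e.g.
#' 6849 genes and 13 brain tissues give 7.30e-6 and 9.49e-5).
#'
#' @param nGenes number of genes tested.
#' @param nTissues number of tissues.
#' @return a \linkS4class{ThresholdSet}.
#' @examples
#' multipleTestingThresholds(6849, 13)
#' @export
multipleTestingThresholds <- function(nGenes, nTissues) {
  if (nGenes < 1 || nTissues < 1) .stopf("counts must be >= 1")
  b <- 0.05 / nGenes
  new("ThresholdSet", bonferroni = b, suggestive = b * nTissues,
      nGenes = as.integer(nGenes), nTissues = as.integer(nTissues))
}

.mrResult <- function(geneId, tissue, subtype, method, beta, se, nSnp,
                      snpIds) {
  new("MRResult", geneId = geneId, tissue = tissue, subtype = subtype,
      method = method, beta = beta, se = se, or = exp(beta),
      ciLow = exp(beta - .Z95 * se), ciHigh = exp(beta + .Z95 * se),
      pval = .pFromZ(beta / se), nSnp = as.integer(nSnp), snpIds = snpIds)
}

#' Two-sample MR estimate for one instrument against one outcome
#'
#' With a single instrument SNP the estimate is its Wald ratio; with several,
#' per-SNP Wald ratios are combined by fixed-effect IVW.  The outcome table
#' must already be harmonised to the instrument's effect alleles and contain
#' every instrument SNP.  OR, 95\% CI and P are filled from \code{beta} and
#' \code{se} using the normal reference.
#'
#' @param instrument a non-empty \linkS4class{Instrument}.
#' @param outcome harmonised outcome \linkS4class{SumStats}.
#' @param subtype outcome subtype label carried into the result.
#' @param seMethod Wald-ratio SE variant (see \code{\link{waldRatio}}).
#' @return an \linkS4class{MRResult}.
#' @export
mrForInstrument <- function(instrument, outcome, subtype = "all",
                            seMethod = c("first_order", "second_order")) {
  stopifnot(is(instrument, "Instrument"), is(outcome, "SumStats"))
  seMethod <- match.arg(seMethod)
  ins <- instrument@records
  if (nrow(ins) == 0L) .stopf("empty instrument for %s", instrument@geneId)
  idx <- match(ins$snp, outcome@records$snp)
  if (anyNA(idx))
    .stopf("instrument SNP(s) missing from outcome: %s",
           paste(ins$snp[is.na(idx)], collapse = ", "))
  out <- outcome@records[idx, , drop = FALSE]
  ratios <- lapply(seq_len(nrow(ins)), function(i)
    waldRatio(ins$beta[i], ins$se[i], out$beta[i], out$se[i], seMethod))
  if (nrow(ins) == 1L) {
    est <- ratios[[1]]
    method <- "wald_ratio"
  } else {
    est <- ivw(vapply(ratios, `[[`, numeric(1), "beta"),
               vapply(ratios, `[[`, numeric(1), "se"))
    method <- "ivw"
  }
  .mrResult(instrument@geneId, instrument@tissue, subtype, method,
            est$beta, est$se, nrow(ins), ins$snp)
}

#' Flatten MRResult objects to the Table-1-shaped results data.frame
#' @param results list of \linkS4class{MRResult}.
#' @return data.frame with columns GENE, SNPS, TISSUE, SUBTYPE, OR, CI_LOW,
#'   CI_HIGH, P, METHOD, N_SNP.
#' @export
mrResultsTable <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(GENE = r@geneId, SNPS = paste(r@snpIds, collapse = ","),
               TISSUE = r@tissue, SUBTYPE = r@subtype, OR = r@or,
               CI_LOW = r@ciLow, CI_HIGH = r@ciHigh, P = r@pval,
               METHOD = r@method, N_SNP = r@nSnp,
               stringsAsFactors = FALSE)))
}
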