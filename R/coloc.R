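#' @include conditional.R
NULL

#' Construct colocalisation priors
#'
#' Defaults are the conventional per-SNP priors: \code{p1 = p2 = 1e-4}
#' (association with one trait), \code{p12 = 1e-5} (association with both),
#' with prior effect SDs 0.15 (quantitative traits, SD units) and 0.2
#' (case-control traits, log-odds units).  A warning (not an error) is given
#' when \code{p12 > min(p1, p2)}, which is rarely a sensible prior.
#'
#' @param p1,p2,p12 per-SNP prior probabilities in (0, 1).
#' @param priorSdQuant,priorSdCc prior effect standard deviations.
#' @return a \linkS4class{ColocPriors}.
#' @export
colocPriors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                        priorSdQuant = 0.15, priorSdCc = 0.2) {
  if (p12 > min(p1, p2))
    warning("p12 exceeds min(p1, p2); check your priors", call. = FALSE)
  new("ColocPriors", p1 = p1, p2 = p2, p12 = p12,
      priorSdQuant = priorSdQuant, priorSdCc = priorSdCc)
}

#' Log approximate Bayes factor for a single association
#'
#' Shrinkage Bayes factor for one SNP: with \code{V = se^2}, \code{W =
#' priorSd^2}, \code{r = W/(V+W)} and \code{z = beta/se},
#' \code{log ABF = 0.5 * (log(1 - r) + r * z^2)}.  Monotone increasing in
#' |z| for fixed r; tends to 0 as the prior SD vanishes.
#'
#' @param beta,se effect estimate and standard error (se > 0).
#' @param priorSd prior effect standard deviation (> 0).
#' @return log approximate Bayes factor (vectorised over inputs).
#' @examples
#' logABF(0.4, 0.1, 0.2)  # z = 4, r = 0.8 -> 0.5*(log 0.2 + 12.8)
#' @export
logABF <- function(beta, se, priorSd) {
  if (any(se <= 0)) .stopf("se must be > 0")
  if (any(priorSd <= 0)) .stopf("priorSd must be > 0")
  V <- se^2
  W <- priorSd^2
  r <- W / (V + W)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

.regionStats <- function(x) {
  if (is(x, "ConditionalRegion")) {
    rec <- x@base@sumstats@records
    keep <- !(rec$snp %in% x@conditionedOn)
    list(snp = rec$snp[keep], beta = x@betaCond[keep],
         se = ifelse(is.finite(x@seCond[keep]), x@seCond[keep],
                     rec$se[keep]),
         traitType = x@base@sumstats@traitType)
  } else if (is(x, "Region")) {
    rec <- x@sumstats@records
    list(snp = rec$snp, beta = rec$beta, se = rec$se,
         traitType = x@sumstats@traitType)
  } else .stopf("expected a Region or ConditionalRegion")
}

#' Bayesian colocalisation of two regions via approximate Bayes factors
#'
#' Evaluates the five single-causal-variant hypotheses for a pair of traits
#' over a shared SNP set: H0 no association, H1/H2 association with one
#' trait only, H3 two distinct causal variants, H4 one shared causal variant.
#' Per-SNP log ABFs are computed for each trait (prior SD chosen by trait
#' type) and combined, entirely in log space, into the unnormalised weights
#' \code{H0 = 1}, \code{H1 = p1 * S1}, \code{H2 = p2 * S2}, \code{H3 = p1 p2
#' (S1 S2 - S12)}, \code{H4 = p12 * S12} where \code{S1 = sum_j L1_j},
#' \code{S2 = sum_j L2_j} and \code{S12 = sum_j L1_j L2_j}; the posteriors
#' are the normalised weights.
#'
#' @param regionX,regionY \linkS4class{Region} or
#'   \linkS4class{ConditionalRegion} objects over identical ordered SNP sets
#'   (harmonise first).  For a ConditionalRegion the conditional statistics
#'   are used and conditioned-out SNPs are excluded from both traits.
#' @param priors a \linkS4class{ColocPriors}.
#' @return a \linkS4class{ColocResult}.
#' @export
colocABF <- function(regionX, regionY, priors = colocPriors()) {
  sx <- .regionStats(regionX)
  sy <- .regionStats(regionY)
  shared <- intersect(sx$snp, sy$snp)
  if (!length(shared)) .stopf("no shared SNPs between the two regions")
  ix <- match(shared, sx$snp); iy <- match(shared, sy$snp)
  if (!identical(sx$snp[ix], sy$snp[iy]))
    .stopf("SNP sets cannot be aligned")
  sdFor <- function(tt) if (tt == "binary") priors@priorSdCc
                        else priors@priorSdQuant
  l1 <- logABF(sx$beta[ix], sx$se[ix], sdFor(sx$traitType))
  l2 <- logABF(sy$beta[iy], sy$se[iy], sdFor(sy$traitType))
  logS1 <- .logsumexp(l1)
  logS2 <- .logsumexp(l2)
  logS12 <- .logsumexp(l1 + l2)
  logW <- c(h0 = 0,
            h1 = log(priors@p1) + logS1,
            h2 = log(priors@p2) + logS2,
            h3 = log(priors@p1) + log(priors@p2) +
              .logdiffexp(logS1 + logS2, logS12),
            h4 = log(priors@p12) + logS12)
  post <- exp(logW - .logsumexp(logW))
  post <- post / sum(post)
  new("ColocResult", posteriors = post, nSnps = length(shared),
      priors = priors)
}

#' Classify colocalisation evidence from the H4 posterior
#'
#' Strong evidence iff H4 >= 0.80 (boundary inclusive); moderate for
#' 0.50 <= H4 < 0.80; weak for H4 < 0.50.
#'
#' @param h4 posterior probability of a shared causal variant, in [0, 1].
#' @return \code{"strong"}, \code{"moderate"} or \code{"weak"}.
#' @export
classifyColoc <- function(h4) {
  if (!is.finite(h4) || h4 < 0 || h4 > 1) .stopf("h4 must lie in [0, 1]")
  if (h4 >= 0.80) "strong" else if (h4 >= 0.50) "moderate" else "weak"
}
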