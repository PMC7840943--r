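#' @include AllClasses.R utils.R
NULL

#' Variance explained by a SNP from its summary statistics
#'
#' With \code{z = beta/se}, \code{r2 = z^2 / (z^2 + n - 2)}; lies in [0, 1).
#' For binary traits pass the effective sample size
#' \code{4/(1/nCase + 1/nControl)} (observed-scale r2).
#'
#' @param beta,se effect estimate and standard error.
#' @param n sample size (> 2).
#' @return variance explained (vectorised).
#' @examples
#' varianceExplained(0.5, 0.1, 1000)  # z = 5 -> 25/1023
#' @export
varianceExplained <- function(beta, se, n) {
  if (any(n <= 2)) .stopf("n must be > 2")
  if (any(se <= 0)) .stopf("se must be > 0")
  z2 <- (beta / se)^2
  z2 / (z2 + n - 2)
}

#' Steiger directionality filter
#'
#' Tests whether the instrument explains more variance in the exposure than
#' in the outcome, guarding against reverse causation.  The two variance-
#' explained values are compared as independent-sample correlations via
#' Fisher transforms: \code{z = (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
#' sqrt(1/(nx-3) + 1/(ny-3))} with a two-sided normal P.  Category is
#' \code{"true"} iff r2x > r2y and P < 0.05, \code{"false"} iff r2x < r2y and
#' P < 0.05, \code{"uncertain"} iff P >= 0.05.  For multi-SNP instruments sum
#' the per-SNP r2 values before calling.
#'
#' @param r2x,r2y variance explained in exposure and outcome, in [0, 1).
#' @param nx,ny sample sizes (> 3; effective n for binary traits).
#' @return a \linkS4class{SteigerResult}.
#' @export
steigerFilter <- function(r2x, nx, r2y, ny) {
  if (any(c(r2x, r2y) < 0) || any(c(r2x, r2y) >= 1))
    .stopf("r2 values must lie in [0, 1)")
  if (nx <= 3 || ny <= 3) .stopf("sample sizes must be > 3")
  z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
    sqrt(1 / (nx - 3) + 1 / (ny - 3))
  p <- .pFromZ(z)
  category <- if (p >= 0.05) "uncertain"
              else if (r2x > r2y) "true" else "false"
  new("SteigerResult", r2Exposure = r2x, r2Outcome = r2y, z = z, pval = p,
      category = category)
}

#' Steiger filtering for an instrument against a harmonised outcome
#'
#' Sums per-SNP variance explained across the instrument SNPs on each side
#' (observed scale; binary outcome uses the effective sample size recorded in
#' the outcome metadata or computed from its case/control counts) and applies
#' \code{\link{steigerFilter}}.
#'
#' @param instrument an \linkS4class{Instrument}.
#' @param outcome harmonised outcome \linkS4class{SumStats} containing the
#'   instrument SNPs.
#' @return a \linkS4class{SteigerResult}.
#' @export
steigerForInstrument <- function(instrument, outcome) {
  stopifnot(is(instrument, "Instrument"), is(outcome, "SumStats"))
  ins <- instrument@records
  if (nrow(ins) == 0L) .stopf("empty instrument")
  idx <- match(ins$snp, outcome@records$snp)
  if (anyNA(idx))
    .stopf("instrument SNP(s) missing from outcome: %s",
           paste(ins$snp[is.na(idx)], collapse = ", "))
  out <- outcome@records[idx, , drop = FALSE]
  nx <- stats::median(ins$n)
  ny <- if (!is.null(outcome@metadata$nEff)) outcome@metadata$nEff
        else if (out$nCase[1] > 0 && out$nControl[1] > 0)
          4 / (1 / out$nCase[1] + 1 / out$nControl[1])
        else stats::median(out$n)
  r2x <- min(sum(varianceExplained(ins$beta, ins$se, nx)), 1 - 1e-12)
  r2y <- min(sum(varianceExplained(out$beta, out$se, ny)), 1 - 1e-12)
  steigerFilter(r2x, nx, r2y, ny)
}
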