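## 95% normal quantile used throughout for CIs (normal, not t, reference).
.Z95 <- 1.959964

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

## log(exp(a) - exp(b)) for a >= b; -Inf when the difference underflows.
.logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

.pFromZ <- function(z) 2 * stats::pnorm(-abs(z))

## Deterministic numeric formatting for TSV writers.
.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == round(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    sprintf("%.10g", v)
  }, character(1))
  out
}

.writeTsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- .fmtNum(df[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

## Complement of A/C/G/T codes.
.allComp <- c(A = "T", C = "G", G = "C", T = "A")

.isPalindromic <- function(ea, oa) .allComp[ea] == oa

#' Two-sided P value implied by an odds ratio and its 95\% CI
#'
#' Reconstructs the Wald z statistic from a printed odds ratio and confidence
#' interval: the standard error is \code{(log(hi) - log(lo)) / (2 * 1.959964)}
#' and the point estimate is, by default, the log-scale midpoint of the CI
#' (the geometric mean of the bounds), which is less sensitive to the coarser
#' rounding usually applied to the printed OR than the OR itself.
#'
#' @param or printed odds ratio.
#' @param ciLow,ciHigh printed 95\% CI bounds.
#' @param betaFrom \code{"ci_midpoint"} (default) or \code{"or"}.
#' @return two-sided normal P value.
#' @examples
#' pFromORCI(0.57, 0.44, 0.74)
#' @export
pFromORCI <- function(or, ciLow, ciHigh, betaFrom = c("ci_midpoint", "or")) {
  betaFrom <- match.arg(betaFrom)
  if (any(c(or, ciLow, ciHigh) <= 0)) .stopf("OR and CI bounds must be > 0")
  if (ciHigh <= ciLow) .stopf("ciHigh must exceed ciLow")
  se <- (log(ciHigh) - log(ciLow)) / (2 * .Z95)
  beta <- if (betaFrom == "ci_midpoint") (log(ciHigh) + log(ciLow)) / 2
          else log(or)
  .pFromZ(beta / se)
}

#' Subtype case bookkeeping for a case-control outcome collection
#'
#' Checks that subtype case counts are consistent with the total and returns
#' the number of cases left unclassified, e.g. 7400 total glioma cases with
#' 3112 GBM and 2411 non-GBM leaves 1877 without subtype diagnosis.
#'
#' @param totalCases total number of cases.
#' @param subtypeCases named or unnamed vector of subtype case counts.
#' @return list with \code{unclassified} and the echoed counts.
#' @examples
#' subtypeCaseCounts(7400, c(gbm = 3112, non_gbm = 2411))$unclassified
#' @export
subtypeCaseCounts <- function(totalCases, subtypeCases) {
  if (totalCases < 0 || any(subtypeCases < 0))
    .stopf("case counts must be nonnegative")
  un <- totalCases - sum(subtypeCases)
  if (un < 0)
    .stopf("subtype cases (%d) exceed total cases (%d)",
           sum(subtypeCases), totalCases)
  list(totalCases = totalCases, subtypeCases = subtypeCases,
       unclassified = un)
}
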