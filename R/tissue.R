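#' @include AllClasses.R utils.R
NULL

#' Cochran's Q heterogeneity test
#'
#' Fixed-effect heterogeneity statistic across k independent estimates:
#' \code{w_i = 1/se_i^2}, \code{thetaBar = sum(w b)/sum(w)},
#' \code{Q = sum(w (b - thetaBar)^2)}, df = k - 1, P from the chi-square
#' upper tail.  Q is invariant under re-ordering and under common rescaling
#' of all (beta, se) pairs.
#'
#' @param betas,ses at least two estimates with positive SEs.
#' @return list with \code{q}, \code{df}, \code{pval}.
#' @examples
#' cochranQ(c(0, 1), c(1, 1))  # Q = 0.5, df = 1, p ~ 0.4795
#' @export
cochranQ <- function(betas, ses) {
  if (length(betas) < 2L) .stopf("need at least 2 estimates")
  if (length(betas) != length(ses)) .stopf("betas and ses lengths differ")
  if (any(ses <= 0)) .stopf("all se must be > 0")
  w <- 1 / ses^2
  tb <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - tb)^2)
  df <- length(betas) - 1L
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Detect tissues whose instrument Z-score opposes the majority sign
#'
#' Per-tissue Z-scores \code{z_i = beta_i/se_i} are signed and a majority
#' sign determined by count; tissues whose sign opposes the majority are
#' returned.  On an exact tie no discordance call is made (a warning is
#' logged and an empty vector returned).
#'
#' @param tissues tissue labels.
#' @param betas,ses per-tissue estimates (>= 3 tissues).
#' @return character vector of discordant tissues (possibly empty).
#' @export
tissueZDiscordance <- function(tissues, betas, ses) {
  if (length(tissues) < 3L) .stopf("need at least 3 tissues")
  if (any(ses <= 0)) .stopf("all se must be > 0")
  z <- betas / ses
  s <- sign(z)
  nPos <- sum(s > 0); nNeg <- sum(s < 0)
  if (nPos == nNeg) {
    warning("exact sign tie across tissues; no discordance call",
            call. = FALSE)
    return(character())
  }
  majority <- if (nPos > nNeg) 1 else -1
  tissues[s == -majority]
}

#' Tissue-specificity tau score
#'
#' \code{xhat_i = x_i / max(x)}; \code{tau = sum(1 - xhat) / (n - 1)}.
#' 0 for uniform expression, 1 for expression confined to a single tissue;
#' scale-invariant.  A gene is called specific when \code{tau >= cutoff}
#' (default 0.8).
#'
#' @param expression per-tissue nonnegative mean expression (>= 2 tissues,
#'   not all zero).
#' @param cutoff specificity cutoff.
#' @param geneId label carried into the result.
#' @return list with \code{geneId}, \code{tau}, \code{nTissues},
#'   \code{specific}.
#' @examples
#' tauScore(c(1, 0, 0, 0))$tau    # 1
#' tauScore(rep(2, 5))$tau        # 0
#' @export
tauScore <- function(expression, cutoff = 0.8, geneId = "gene") {
  if (length(expression) < 2L) .stopf("need at least 2 tissues")
  if (any(expression < 0)) .stopf("expression must be nonnegative")
  mx <- max(expression)
  if (mx <= 0) .stopf("tau undefined for an all-zero expression vector")
  xhat <- expression / mx
  tau <- sum(1 - xhat) / (length(expression) - 1)
  list(geneId = geneId, tau = tau, nTissues = length(expression),
       specific = tau >= cutoff)
}

#' Correlation of MR estimates between two tissue classes across thresholds
#'
#' For each P value threshold t, genes present in both result sets are kept
#' when \code{min(p_a, p_b) < t} under the default \code{"either"} inclusion
#' rule (or when both P values pass under \code{"both"}); the Pearson
#' correlation of the two log-odds effect vectors and the gene count are
#' reported.  Fewer than 3 shared genes at a threshold flags the row as not
#' estimable (NA correlation).
#'
#' @param resultsA,resultsB data.frames with columns \code{gene},
#'   \code{beta}, \code{pval} (one row per gene), e.g. brain-based and
#'   blood-based MR results.
#' @param thresholds P value thresholds in (0, 1]; the default is the
#'   four-threshold ladder 0.1, 0.05, 0.01, 0.005.
#' @param rule \code{"either"} (default) or \code{"both"}.
#' @return data.frame with columns THRESHOLD, PEARSON_R, N_GENES, plus OR
#'   columns are the caller's concern (effects here are log-odds).
#' @export
brainBloodCorrelation <- function(resultsA, resultsB,
                                  thresholds = c(0.1, 0.05, 0.01, 0.005),
                                  rule = c("either", "both")) {
  rule <- match.arg(rule)
  if (any(thresholds <= 0 | thresholds > 1))
    .stopf("thresholds must lie in (0, 1]")
  need <- c("gene", "beta", "pval")
  if (!all(need %in% names(resultsA)) || !all(need %in% names(resultsB)))
    .stopf("results need columns gene, beta, pval")
  shared <- intersect(resultsA$gene, resultsB$gene)
  a <- resultsA[match(shared, resultsA$gene), , drop = FALSE]
  b <- resultsB[match(shared, resultsB$gene), , drop = FALSE]
  rows <- lapply(thresholds, function(t) {
    keep <- if (rule == "either") pmin(a$pval, b$pval) < t
            else a$pval < t & b$pval < t
    n <- sum(keep)
    r <- if (n >= 3) stats::cor(a$beta[keep], b$beta[keep]) else NA_real_
    data.frame(THRESHOLD = t, PEARSON_R = r, N_GENES = n,
               ESTIMABLE = n >= 3)
  })
  do.call(rbind, rows)
}
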