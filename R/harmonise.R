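#' @include sumstats-io.R
NULL

#' Harmonise exposure and outcome summary statistics
#'
#' Intersects the two tables on SNP id and aligns the outcome's effect allele
#' to the exposure's.  Where the outcome's effect/other alleles are swapped,
#' the outcome beta sign is flipped and \code{eaf <- 1 - eaf}; complementary
#' (strand-flipped) codings are recoded to the exposure strand first.
#' Palindromic SNPs (A/T or G/C) are dropped as ambiguous when both effect
#' allele frequencies lie within \code{palindromeEafWindow} of 0.5, and are
#' otherwise aligned by frequency (flipping the outcome when the frequencies
#' are on opposite sides of 0.5).  Variants whose allele pairs cannot be
#' reconciled are dropped.  Every drop is recorded with a reason.
#'
#' @param exposure,outcome \linkS4class{SumStats} objects.
#' @param palindromeEafWindow half-width of the ambiguity window around 0.5
#'   (default 0.08, i.e. EAF in [0.42, 0.58] drops a palindromic SNP).
#' @return a \linkS4class{HarmonisedPair}.
#' @export
harmonise <- function(exposure, outcome, palindromeEafWindow = 0.08) {
  stopifnot(is(exposure, "SumStats"), is(outcome, "SumStats"))
  ex <- exposure@records
  ou <- outcome@records
  if (nrow(ex) == 0L || nrow(ou) == 0L)
    .stopf("both tables must be non-empty")
  shared <- intersect(ex$snp, ou$snp)
  dropped <- data.frame(snp = character(), reason = character(),
                        stringsAsFactors = FALSE)
  drop1 <- function(snp, reason)
    rbind(dropped, data.frame(snp = snp, reason = reason,
                              stringsAsFactors = FALSE))
  only <- setdiff(union(ex$snp, ou$snp), shared)
  if (length(only))
    dropped <- drop1(only, "absent from one table")
  if (length(shared) == 0L)
    .stopf("no shared SNPs between %s and %s", exposure@traitId,
           outcome@traitId)
  ex <- ex[match(shared, ex$snp), , drop = FALSE]
  ou <- ou[match(shared, ou$snp), , drop = FALSE]

  keep <- rep(TRUE, length(shared))
  for (i in seq_along(shared)) {
    eaX <- ex$ea[i]; oaX <- ex$oa[i]
    eaY <- ou$ea[i]; oaY <- ou$oa[i]
    pal <- .isPalindromic(eaX, oaX)
    flip <- FALSE
    if (eaY == eaX && oaY == oaX) {
      flip <- FALSE
    } else if (eaY == oaX && oaY == eaX) {
      flip <- TRUE
    } else if (!pal && .allComp[eaY] == eaX && .allComp[oaY] == oaX) {
      flip <- FALSE            # strand flip, same orientation
    } else if (!pal && .allComp[eaY] == oaX && .allComp[oaY] == eaX) {
      flip <- TRUE             # strand flip, swapped orientation
    } else {
      keep[i] <- FALSE
      dropped <- drop1(shared[i], "allele mismatch")
      next
    }
    if (pal) {
      ambX <- abs(ex$eaf[i] - 0.5) <= palindromeEafWindow
      ambY <- abs(ou$eaf[i] - 0.5) <= palindromeEafWindow
      if (ambX && ambY) {
        keep[i] <- FALSE
        dropped <- drop1(shared[i], "palindromic, ambiguous")
        next
      }
      ## align by frequency: after any letter-based flip above, the outcome
      ## EAF should fall on the same side of 0.5 as the exposure EAF
      eafY <- if (flip) 1 - ou$eaf[i] else ou$eaf[i]
      if ((ex$eaf[i] < 0.5) != (eafY < 0.5)) flip <- !flip
    }
    if (flip) {
      ou$beta[i] <- -ou$beta[i]
      ou$eaf[i] <- 1 - ou$eaf[i]
    }
    ou$ea[i] <- eaX
    ou$oa[i] <- oaX
  }
  ex <- ex[keep, , drop = FALSE]
  ou <- ou[keep, , drop = FALSE]
  if (nrow(ex) == 0L)
    .stopf("no harmonisable SNPs between %s and %s", exposure@traitId,
           outcome@traitId)
  ## outcome keeps its own chrom/pos fields but aligned identity columns
  ou$chrom <- ex$chrom; ou$pos <- ex$pos
  new("HarmonisedPair",
      exposure = sumStats(exposure@traitId, exposure@traitType, ex,
                          exposure@metadata),
      outcome = sumStats(outcome@traitId, outcome@traitType, ou,
                         outcome@metadata),
      dropped = dropped)
}
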