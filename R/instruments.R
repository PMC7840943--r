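#' @include sumstats-io.R
NULL

#' Construct a GeneAnnotation
#' @param geneId gene identifier.
#' @param chrom chromosome.
#' @param tss 1-based transcription start site (bp).
#' @param symbol optional gene symbol.
#' @return a \linkS4class{GeneAnnotation}.
#' @export
geneAnnotation <- function(geneId, chrom, tss, symbol = geneId) {
  new("GeneAnnotation", geneId = geneId, chrom = as.character(chrom),
      tss = tss, symbol = symbol)
}

#' Read a gene annotation table (GENE, CHR, TSS, SYMBOL)
#' @param path TSV file path.
#' @return list of \linkS4class{GeneAnnotation}, named by gene id.
#' @export
readGeneAnnotation <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  miss <- setdiff(c("GENE", "CHR", "TSS"), names(tab))
  if (length(miss))
    .stopf("annotation missing column(s): %s", paste(miss, collapse = ", "))
  if (is.null(tab$SYMBOL)) tab$SYMBOL <- tab$GENE
  out <- lapply(seq_len(nrow(tab)), function(i)
    geneAnnotation(tab$GENE[i], tab$CHR[i], as.numeric(tab$TSS[i]),
                   tab$SYMBOL[i]))
  names(out) <- tab$GENE
  out
}

#' Restrict summary statistics to the cis window of a gene
#'
#' Retains variants on the gene's chromosome with \code{|pos - tss| <=
#' windowBp} (closed interval: a SNP exactly at the window edge is kept).
#' Trans variants are excluded; the result may be empty.
#'
#' @param sumstats a \linkS4class{SumStats}.
#' @param gene a \linkS4class{GeneAnnotation}.
#' @param windowBp half-width of the cis window in bp (default 1 Mbp).
#' @return a \linkS4class{SumStats} (possibly with zero records).
#' @export
cisFilter <- function(sumstats, gene, windowBp = 1e6) {
  stopifnot(is(sumstats, "SumStats"), is(gene, "GeneAnnotation"))
  if (windowBp <= 0) .stopf("windowBp must be > 0")
  rec <- sumstats@records
  keep <- rec$chrom == gene@chrom & abs(rec$pos - gene@tss) <= windowBp
  sumStats(sumstats@traitId, sumstats@traitType,
           rec[keep, , drop = FALSE], sumstats@metadata)
}

#' Greedy LD clumping of significant variants
#'
#' Candidates with \code{pval < pThreshold} are sorted by ascending P value
#' (ties broken by ascending position, then SNP id) and accepted greedily: a
#' SNP is kept iff its squared correlation with every previously accepted SNP
#' is below \code{r2Threshold}.  The result is invariant under input row
#' order because the sort order is total.
#'
#' @param sumstats a \linkS4class{SumStats}.
#' @param ld an \linkS4class{LDMatrix} covering every candidate SNP.
#' @param pThreshold significance threshold (strict).
#' @param r2Threshold LD pruning threshold on r-squared (strict).
#' @return character vector of accepted SNP ids, in acceptance order.
#' @export
clumpSnps <- function(sumstats, ld, pThreshold, r2Threshold = 0.01) {
  stopifnot(is(sumstats, "SumStats"), is(ld, "LDMatrix"))
  rec <- sumstats@records
  cand <- rec[rec$pval < pThreshold, , drop = FALSE]
  if (nrow(cand) == 0L) return(character())
  missing <- setdiff(cand$snp, ld@snpIds)
  if (length(missing))
    .stopf("SNP(s) missing from the LD matrix: %s",
           paste(missing, collapse = ", "))
  ord <- order(cand$pval, cand$pos, cand$snp)
  cand <- cand[ord, , drop = FALSE]
  idx <- match(cand$snp, ld@snpIds)
  r2 <- ld@r[idx, idx, drop = FALSE]^2
  accepted <- integer()
  for (i in seq_len(nrow(cand))) {
    if (!length(accepted) || all(r2[i, accepted] < r2Threshold))
      accepted <- c(accepted, i)
  }
  cand$snp[accepted]
}

#' Select a cis instrument for one gene
#'
#' Applies the cis-window filter (1 Mbp around the TSS) followed by greedy LD
#' clumping at \code{r2 < 0.01}.  Discovery mode uses genome-wide significance
#' (P < 5e-8); tissue-specific mode uses the lenient threshold P < 5e-4 that
#' admits weaker per-tissue eQTLs.
#'
#' @param sumstats exposure-side \linkS4class{SumStats} (one gene/tissue).
#' @param gene a \linkS4class{GeneAnnotation}.
#' @param ld an \linkS4class{LDMatrix}.
#' @param mode \code{"discovery"} or \code{"tissue_specific"}.
#' @param tissue tissue label stored on the instrument.
#' @param windowBp cis-window half-width.
#' @param r2Threshold clumping threshold.
#' @param pThreshold override the mode's P threshold.
#' @return an \linkS4class{Instrument}; zero rows when no SNP qualifies.
#' @export
selectInstruments <- function(sumstats, gene, ld,
                              mode = c("discovery", "tissue_specific"),
                              tissue = "unknown", windowBp = 1e6,
                              r2Threshold = 0.01, pThreshold = NULL) {
  mode <- match.arg(mode)
  if (is.null(pThreshold))
    pThreshold <- if (mode == "discovery") 5e-8 else 5e-4
  cis <- cisFilter(sumstats, gene, windowBp)
  ids <- if (nrow(cis@records)) clumpSnps(cis, ld, pThreshold, r2Threshold)
         else character()
  rec <- cis@records[match(ids, cis@records$snp), , drop = FALSE]
  rownames(rec) <- NULL
  new("Instrument", geneId = gene@geneId, tissue = tissue, records = rec,
      clumpR2 = r2Threshold, pThreshold = pThreshold)
}
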