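#' @include AllClasses.R
NULL

#' Accessors for mrcoloc S4 containers
#'
#' \code{snpIds} returns the ordered SNP identifiers of a \code{SumStats},
#' \code{LDMatrix}, \code{Instrument} or \code{Region}; \code{records} the
#' per-SNP record data.frame; \code{traitId}/\code{traitType} the trait
#' identity; \code{ldr} the signed correlation matrix; \code{posteriors} the
#' named h0..h4 vector of a \code{ColocResult}.
#'
#' @param x an mrcoloc object.
#' @return See description; accessor-specific.
#' @name accessors
#' @aliases snpIds records traitId traitType ldr posteriors
NULL

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))

#' @rdname accessors
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))

#' @rdname accessors
#' @export
setGeneric("ldr", function(x) standardGeneric("ldr"))

#' @rdname accessors
#' @export
setGeneric("posteriors", function(x) standardGeneric("posteriors"))

setMethod("snpIds", "SumStats", function(x) x@records$snp)
setMethod("snpIds", "LDMatrix", function(x) x@snpIds)
setMethod("snpIds", "Instrument", function(x) x@records$snp)
setMethod("snpIds", "Region", function(x) x@sumstats@records$snp)
setMethod("snpIds", "ConditionalRegion", function(x) snpIds(x@base))

setMethod("records", "SumStats", function(x) x@records)
setMethod("records", "Instrument", function(x) x@records)
setMethod("records", "Region", function(x) x@sumstats@records)

setMethod("traitId", "SumStats", function(x) x@traitId)
setMethod("traitType", "SumStats", function(x) x@traitType)

setMethod("ldr", "LDMatrix", function(x) x@r)

setMethod("posteriors", "ColocResult", function(x) x@posteriors)

#' @export
setMethod("show", "SumStats", function(object) {
  cat(sprintf("SumStats '%s' (%s): %d variants\n", object@traitId,
              object@traitType, nrow(object@records)))
  if (nrow(object@records))
    cat(sprintf("  chrom %s, pos %s..%s\n",
                paste(unique(object@records$chrom), collapse = ","),
                format(min(object@records$pos), big.mark = ","),
                format(max(object@records$pos), big.mark = ",")))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix: %d x %d SNPs\n", nrow(object@r), ncol(object@r)))
})

setMethod("show", "HarmonisedPair", function(object) {
  cat(sprintf("HarmonisedPair: %d shared variants (%d dropped)\n",
              nrow(object@exposure@records), nrow(object@dropped)))
})

setMethod("show", "Instrument", function(object) {
  cat(sprintf("Instrument for %s [%s]: %d SNP(s) (p < %.3g, r2 < %.3g)\n",
              object@geneId, object@tissue, nrow(object@records),
              object@pThreshold, object@clumpR2))
})

setMethod("show", "MRResult", function(object) {
  cat(sprintf(
    "MRResult %s [%s, %s] %s: OR %.3f (%.3f, %.3f), P = %.3g, nSNP = %d\n",
    object@geneId, object@tissue, object@subtype, object@method, object@or,
    object@ciLow, object@ciHigh, object@pval, object@nSnp))
})

setMethod("show", "ColocResult", function(object) {
  h <- object@posteriors
  cat(sprintf("ColocResult (%d SNPs): H0 %.3f H1 %.3f H2 %.3f H3 %.3f H4 %.3f [%s]\n",
              object@nSnps, h[1], h[2], h[3], h[4], h[5],
              classifyColoc(unname(h[5]))))
})

setMethod("show", "SteigerResult", function(object) {
  cat(sprintf(
    "SteigerResult: r2(exposure) %.4g vs r2(outcome) %.4g, z %.3f, P %.3g -> %s\n",
    object@r2Exposure, object@r2Outcome, object@z, object@pval,
    object@category))
})

setMethod("show", "Region", function(object) {
  cat(sprintf("Region chr%s:%s-%s, lead %s, %d SNPs\n", object@chrom,
              format(object@start, big.mark = ","),
              format(object@end, big.mark = ","), object@leadSnp,
              nrow(object@sumstats@records)))
})

setMethod("show", "ConditionalRegion", function(object) {
  cat(sprintf("ConditionalRegion: %d SNPs conditioned on {%s}\n",
              length(object@betaCond),
              paste(object@conditionedOn, collapse = ", ")))
})

setMethod("show", "SimScenario", function(object) {
  cat(sprintf(
    "SimScenario '%s': betaGx %.3g, theta %.3g, n %d / %d:%d\n",
    object@name, object@betaGx, object@theta, object@nExposure,
    object@nCase, object@nControl))
})

setMethod("show", "ThresholdSet", function(object) {
  cat(sprintf("ThresholdSet: bonferroni %.3g (0.05/%d), suggestive %.3g (x%d)\n",
              object@bonferroni, object@nGenes, object@suggestive,
              object@nTissues))
})
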