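#' @import methods
NULL

## Canonical internal column set for per-SNP association records.  The on-disk
## TSV dialect maps these to SNP/CHR/POS/EA/OA/EAF/BETA/SE/P/N/N_CASE/N_CONTROL.
.recordCols <- c("snp", "chrom", "pos", "ea", "oa", "eaf", "beta", "se",
                 "pval", "n", "nCase", "nControl")

.validAlleles <- c("A", "C", "G", "T")

#' SumStats: one trait's marginal per-SNP association records
#'
#' Container for GWAS or eQTL summary statistics of a single trait (a gene in
#' one tissue, or a disease subtype).  Records hold per-variant effect-allele
#' coded estimates: \code{snp}, \code{chrom}, \code{pos} (1-based bp),
#' \code{ea}/\code{oa} (effect/other allele), \code{eaf}, \code{beta}
#' (per-allele effect; log-odds for binary traits), \code{se}, \code{pval},
#' \code{n}, and \code{nCase}/\code{nControl} (0 for quantitative traits).
#'
#' @slot traitId trait identifier, e.g. \code{"GENE1:brain"} or
#'   \code{"all_glioma"}.
#' @slot traitType \code{"quantitative"} or \code{"binary"}.
#' @slot records data.frame of per-SNP records (see Details).
#' @slot metadata free-form list; for binary traits the constructor stores the
#'   effective sample size \code{nEff = 4/(1/nCase + 1/nControl)}.
#' @export
setClass("SumStats",
         slots = c(traitId = "character",
                   traitType = "character",
                   records = "data.frame",
                   metadata = "list"))

setValidity("SumStats", function(object) {
  msg <- character()
  if (length(object@traitId) != 1L || !nzchar(object@traitId))
    msg <- c(msg, "traitId must be a single non-empty string")
  if (!object@traitType %in% c("quantitative", "binary"))
    msg <- c(msg, "traitType must be 'quantitative' or 'binary'")
  rec <- object@records
  miss <- setdiff(.recordCols, names(rec))
  if (length(miss))
    msg <- c(msg, paste0("records missing columns: ",
                         paste(miss, collapse = ", ")))
  if (!length(msg) && nrow(rec)) {
    if (anyDuplicated(rec$snp))
      msg <- c(msg, "snp ids must be unique within a table")
    if (any(!is.finite(rec$se) | rec$se <= 0))
      msg <- c(msg, "all se must be finite and > 0")
    if (any(!is.finite(rec$eaf) | rec$eaf <= 0 | rec$eaf >= 1))
      msg <- c(msg, "all eaf must lie in (0, 1)")
    if (any(!is.finite(rec$pval) | rec$pval <= 0 | rec$pval > 1))
      msg <- c(msg, "all pval must lie in (0, 1]")
    if (any(rec$ea == rec$oa))
      msg <- c(msg, "effect and other allele must differ")
    ## positions non-decreasing within chromosome
    bych <- split(rec$pos, rec$chrom)
    if (any(vapply(bych, is.unsorted, logical(1))))
      msg <- c(msg, "positions must be non-decreasing within a chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' LDMatrix: labelled SNP-by-SNP correlation matrix
#'
#' @slot snpIds ordered SNP identifiers labelling rows/columns.
#' @slot r square numeric matrix of signed pairwise correlations.
#' @export
setClass("LDMatrix",
         slots = c(snpIds = "character", r = "matrix"))

setValidity("LDMatrix", function(object) {
  msg <- character()
  r <- object@r
  if (nrow(r) != ncol(r)) msg <- c(msg, "r must be square")
  if (length(object@snpIds) != nrow(r))
    msg <- c(msg, "snpIds length must match matrix dimension")
  if (anyDuplicated(object@snpIds)) msg <- c(msg, "snpIds must be unique")
  if (!length(msg) && nrow(r)) {
    if (max(abs(r - t(r))) > 1e-8) msg <- c(msg, "r must be symmetric")
    if (max(abs(diag(r) - 1)) > 1e-8) msg <- c(msg, "diagonal must be 1")
    if (max(abs(r)) > 1 + 1e-8) msg <- c(msg, "entries must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' HarmonisedPair: exposure/outcome tables on a shared, allele-aligned SNP set
#'
#' @slot exposure,outcome \linkS4class{SumStats} restricted to the shared SNPs,
#'   with the outcome's effect alleles aligned to the exposure's.
#' @slot dropped data.frame with columns \code{snp}, \code{reason} recording
#'   every variant removed during harmonisation.
#' @export
setClass("HarmonisedPair",
         slots = c(exposure = "SumStats", outcome = "SumStats",
                   dropped = "data.frame"))

setValidity("HarmonisedPair", function(object) {
  ex <- object@exposure@records; ou <- object@outcome@records
  msg <- character()
  if (!identical(ex$snp, ou$snp))
    msg <- c(msg, "exposure and outcome must share identical ordered snp ids")
  else if (nrow(ex) && (any(ex$ea != ou$ea) || any(ex$oa != ou$oa)))
    msg <- c(msg, "effect alleles must be identical across the pair")
  if (!all(c("snp", "reason") %in% names(object@dropped)))
    msg <- c(msg, "dropped must have columns snp, reason")
  if (length(msg)) msg else TRUE
})

#' GeneAnnotation: minimal per-gene annotation for cis-window filtering
#' @slot geneId,chrom,symbol character scalars.
#' @slot tss 1-based transcription start site (bp).
#' @export
setClass("GeneAnnotation",
         slots = c(geneId = "character", chrom = "character",
                   tss = "numeric", symbol = "character"))

setValidity("GeneAnnotation", function(object) {
  if (object@tss < 1) "tss must be >= 1" else TRUE
})

#' Instrument: clumped cis instrument for one gene in one tissue
#'
#' @slot geneId,tissue identifiers.
#' @slot records exposure-side \linkS4class{SumStats} records of the selected
#'   SNPs, in acceptance order (possibly zero rows).
#' @slot clumpR2,pThreshold the selection parameters used.
#' @export
setClass("Instrument",
         slots = c(geneId = "character", tissue = "character",
                   records = "data.frame", clumpR2 = "numeric",
                   pThreshold = "numeric"))

#' MRResult: per gene-tissue-subtype causal-effect estimate
#'
#' Invariants: \code{or = exp(beta)}, \code{ciLow/ciHigh = exp(beta -/+
#' 1.959964*se)}, \code{pval} the two-sided normal tail of \code{beta/se}.
#'
#' @slot geneId,tissue,subtype identifiers.
#' @slot method \code{"wald_ratio"} or \code{"ivw"}.
#' @slot beta,se log-odds per SD expression and its standard error.
#' @slot or,ciLow,ciHigh,pval derived odds ratio, 95\% CI and P value.
#' @slot nSnp number of instrument SNPs; @slot snpIds their ids.
#' @export
setClass("MRResult",
         slots = c(geneId = "character", tissue = "character",
                   subtype = "character", method = "character",
                   beta = "numeric", se = "numeric", or = "numeric",
                   ciLow = "numeric", ciHigh = "numeric", pval = "numeric",
                   nSnp = "integer", snpIds = "character"))

setValidity("MRResult", function(object) {
  msg <- character()
  if (!object@method %in% c("wald_ratio", "ivw"))
    msg <- c(msg, "method must be 'wald_ratio' or 'ivw'")
  if (object@se <= 0) msg <- c(msg, "se must be > 0")
  z <- .Z95
  ok <- isTRUE(all.equal(object@or, exp(object@beta), tolerance = 1e-9)) &&
    isTRUE(all.equal(object@ciLow, exp(object@beta - z * object@se),
                     tolerance = 1e-9)) &&
    isTRUE(all.equal(object@ciHigh, exp(object@beta + z * object@se),
                     tolerance = 1e-9))
  if (!ok) msg <- c(msg, "or/ci fields inconsistent with beta and se")
  if (object@nSnp < 1L) msg <- c(msg, "nSnp must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ThresholdSet: Bonferroni and suggestive significance thresholds
#'
#' \code{bonferroni = 0.05 / nGenes}; \code{suggestive = bonferroni * nTissues}.
#' @export
setClass("ThresholdSet",
         slots = c(bonferroni = "numeric", suggestive = "numeric",
                   nGenes = "integer", nTissues = "integer"))

#' Region: summary-statistic slice around a lead SNP
#'
#' Closed 1-based interval \code{[start, end]}; every record lies inside it and
#' the lead SNP is present.
#' @export
setClass("Region",
         slots = c(sumstats = "SumStats", chrom = "character",
                   start = "numeric", end = "numeric", leadSnp = "character"))

setValidity("Region", function(object) {
  rec <- object@sumstats@records
  msg <- character()
  if (!object@leadSnp %in% rec$snp) msg <- c(msg, "lead SNP absent from region")
  if (nrow(rec) && (any(rec$pos < object@start) || any(rec$pos > object@end)))
    msg <- c(msg, "records outside [start, end]")
  if (length(msg)) msg else TRUE
})

#' ConditionalRegion: region statistics conditioned on a set of SNPs
#'
#' Vectors are aligned to the base region's SNP order; SNPs in
#' \code{conditionedOn} have \code{betaCond = 0}.
#' @export
setClass("ConditionalRegion",
         slots = c(base = "Region", conditionedOn = "character",
                   betaCond = "numeric", seCond = "numeric",
                   pCond = "numeric"))

#' ColocPriors: per-SNP priors and effect-size prior SDs for colocalisation
#'
#' @slot p1,p2 prior probability a SNP is associated with trait 1 / trait 2.
#' @slot p12 prior probability a SNP is associated with both.
#' @slot priorSdQuant,priorSdCc prior effect SD for quantitative (SD units)
#'   and case-control (log-odds) traits.
#' @export
setClass("ColocPriors",
         slots = c(p1 = "numeric", p2 = "numeric", p12 = "numeric",
                   priorSdQuant = "numeric", priorSdCc = "numeric"))

setValidity("ColocPriors", function(object) {
  v <- c(object@p1, object@p2, object@p12)
  if (any(v <= 0 | v >= 1)) return("p1, p2, p12 must lie in (0, 1)")
  if (object@priorSdQuant <= 0 || object@priorSdCc <= 0)
    return("prior SDs must be > 0")
  TRUE
})

#' ColocResult: posterior probabilities of the five colocalisation hypotheses
#'
#' H0: no association; H1/H2: association with one trait only; H3: two
#' distinct causal variants; H4: one shared causal variant.
#' @export
setClass("ColocResult",
         slots = c(posteriors = "numeric", nSnps = "integer",
                   priors = "ColocPriors"))

setValidity("ColocResult", function(object) {
  h <- object@posteriors
  if (length(h) != 5L || !identical(names(h), paste0("h", 0:4)))
    return("posteriors must be named h0..h4")
  if (any(h < -1e-12 | h > 1 + 1e-12)) return("posteriors must lie in [0, 1]")
  if (abs(sum(h) - 1) > 1e-9) return("posteriors must sum to 1 within 1e-9")
  TRUE
})

#' SteigerResult: directionality test result
#'
#' Category is \code{"true"} iff the instrument explains more variance in the
#' exposure than the outcome with P < 0.05, \code{"false"} for the reverse,
#' \code{"uncertain"} when P >= 0.05.
#' @export
setClass("SteigerResult",
         slots = c(r2Exposure = "numeric", r2Outcome = "numeric",
                   z = "numeric", pval = "numeric", category = "character"))

#' SimScenario: generative configuration for one synthetic study pair
#'
#' @slot name one of \code{"null"}, \code{"exposure_only"},
#'   \code{"outcome_only"}, \code{"distinct_variants"},
#'   \code{"shared_variant"}.
#' @slot causalSnpExposure,causalSnpOutcome 1-based SNP indices (NA if absent).
#' @slot betaGx effect of the causal SNP on the exposure (SD expression per
#'   allele); @slot betaGy direct log-odds-per-allele effect of the outcome's
#'   own causal SNP (outcome_only / distinct_variants).
#' @slot theta causal effect of exposure on outcome (log-odds per SD
#'   expression); used only under \code{shared_variant}.
#' @slot nExposure,nCase,nControl sample sizes.
#' @slot mafRange pair in (0, 0.5] from which MAFs are drawn uniformly.
#' @export
setClass("SimScenario",
         slots = c(name = "character",
                   causalSnpExposure = "integer", causalSnpOutcome = "integer",
                   betaGx = "numeric", betaGy = "numeric", theta = "numeric",
                   nExposure = "integer", nCase = "integer",
                   nControl = "integer", mafRange = "numeric"))

.scenarioNames <- c("null", "exposure_only", "outcome_only",
                    "distinct_variants", "shared_variant")

setValidity("SimScenario", function(object) {
  msg <- character()
  if (!object@name %in% .scenarioNames)
    msg <- c(msg, paste("name must be one of:",
                        paste(.scenarioNames, collapse = ", ")))
  if (object@name %in% c("exposure_only", "distinct_variants",
                         "shared_variant") &&
      is.na(object@causalSnpExposure))
    msg <- c(msg, "scenario requires causalSnpExposure")
  if (object@name %in% c("outcome_only", "distinct_variants") &&
      is.na(object@causalSnpOutcome))
    msg <- c(msg, "scenario requires causalSnpOutcome")
  if (object@name == "distinct_variants" &&
      !is.na(object@causalSnpExposure) && !is.na(object@causalSnpOutcome) &&
      object@causalSnpExposure == object@causalSnpOutcome)
    msg <- c(msg, "distinct_variants requires distinct causal SNP indices")
  if (any(c(object@nExposure, object@nCase + object@nControl) < 4L))
    msg <- c(msg, "all sample sizes must be >= 4")
  mr <- object@mafRange
  if (length(mr) != 2L || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
    msg <- c(msg, "mafRange must be an increasing pair within (0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' SimTruth: the ground-truth sidecar of a simulated study pair
#' @slot trueWaldEffect theta under shared_variant, 0 otherwise.
#' @export
setClass("SimTruth",
         slots = c(scenario = "SimScenario", trueWaldEffect = "numeric",
                   seed = "integer"))
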