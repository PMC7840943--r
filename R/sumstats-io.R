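#' @include AllClasses.R utils.R
NULL

## TSV header -> internal column mapping of the canonical dialect.
.tsvCols <- c(SNP = "snp", CHR = "chrom", POS = "pos", EA = "ea", OA = "oa",
              EAF = "eaf", BETA = "beta", SE = "se", P = "pval", N = "n",
              N_CASE = "nCase", N_CONTROL = "nControl")

#' Construct a SumStats object
#'
#' Builds a validated \linkS4class{SumStats} from a data.frame of per-SNP
#' records.  Records are sorted by chromosome then position.  For binary
#' traits the effective sample size \code{nEff = 4/(1/nCase + 1/nControl)}
#' (the standard meta-analysis convention) is stored in \code{metadata$nEff},
#' taken from the first record.
#'
#' @param traitId trait identifier.
#' @param traitType \code{"quantitative"} or \code{"binary"}.
#' @param records data.frame with columns \code{snp, chrom, pos, ea, oa, eaf,
#'   beta, se, pval, n, nCase, nControl} (the last two optional, default 0).
#' @param metadata optional list of free-form metadata.
#' @return a \linkS4class{SumStats}.
#' @export
sumStats <- function(traitId, traitType, records, metadata = list()) {
  if (is.null(records$nCase)) records$nCase <- 0L
  if (is.null(records$nControl)) records$nControl <- 0L
  records <- records[, .recordCols]
  records$chrom <- as.character(records$chrom)
  records$snp <- as.character(records$snp)
  records <- records[order(records$chrom, records$pos, records$snp), ,
                     drop = FALSE]
  rownames(records) <- NULL
  if (traitType == "binary" && nrow(records) &&
      records$nCase[1] > 0 && records$nControl[1] > 0)
    metadata$nEff <- 4 / (1 / records$nCase[1] + 1 / records$nControl[1])
  new("SumStats", traitId = traitId, traitType = traitType,
      records = records, metadata = metadata)
}

.checkRecordRow <- function(rec) {
  ## vectorised per-row rejection reasons; "" when the row is acceptable
  reason <- rep("", nrow(rec))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    ifelse(cond & reason == "", why, reason)
  }
  reason <- bad(!is.finite(rec$se) | rec$se <= 0, "nonpositive SE")
  reason <- bad(!is.finite(rec$eaf) | rec$eaf <= 0 | rec$eaf >= 1,
                "EAF outside (0,1)")
  reason <- bad(!is.finite(rec$pval) | rec$pval <= 0 | rec$pval > 1,
                "P outside (0,1]")
  reason <- bad(!rec$ea %in% .validAlleles | !rec$oa %in% .validAlleles,
                "invalid allele code")
  reason <- bad(rec$ea == rec$oa, "identical alleles")
  reason <- bad(!is.finite(rec$beta), "non-finite beta")
  reason <- bad(!is.finite(rec$pos) | rec$pos < 1, "invalid position")
  reason
}

#' Read summary statistics from the canonical TSV dialect
#'
#' Parses a tab-delimited table with mandatory columns \code{SNP, CHR, POS,
#' EA, OA, EAF, BETA, SE, P, N} (plus \code{N_CASE, N_CONTROL} for binary
#' traits; absent columns default to 0).  Scientific notation is accepted.
#' Rows violating per-variant invariants (nonpositive SE, out-of-range EAF or
#' P, invalid alleles) are removed and reported via the \code{"rejected"}
#' attribute and a warning.  A consistency warning (not an error) is emitted
#' for rows whose stated P disagrees with the two-sided normal approximation
#' from beta/SE by more than a factor of 2, since rounded published tables
#' violate exact consistency.
#'
#' @param path file path.
#' @param traitType \code{"quantitative"} or \code{"binary"}.
#' @param traitId optional trait id; defaults to the file name.
#' @return a \linkS4class{SumStats}; rejected rows (with reasons) in
#'   \code{attr(, "rejected")}.
#' @export
readSumStats <- function(path, traitType = c("quantitative", "binary"),
                         traitId = NULL) {
  traitType <- match.arg(traitType)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  mand <- setdiff(names(.tsvCols), c("N_CASE", "N_CONTROL"))
  miss <- setdiff(mand, names(raw))
  if (length(miss))
    .stopf("missing mandatory column(s): %s", paste(miss, collapse = ", "))
  if (nrow(raw) == 0L) .stopf("empty summary-statistics table: %s", path)
  rec <- data.frame(snp = raw$SNP, chrom = raw$CHR,
                    pos = as.numeric(raw$POS),
                    ea = toupper(raw$EA), oa = toupper(raw$OA),
                    eaf = as.numeric(raw$EAF), beta = as.numeric(raw$BETA),
                    se = as.numeric(raw$SE), pval = as.numeric(raw$P),
                    n = as.numeric(raw$N),
                    nCase = if (is.null(raw$N_CASE)) 0
                            else as.numeric(raw$N_CASE),
                    nControl = if (is.null(raw$N_CONTROL)) 0
                               else as.numeric(raw$N_CONTROL),
                    stringsAsFactors = FALSE)
  reason <- .checkRecordRow(rec)
  rejected <- data.frame(snp = rec$snp[reason != ""],
                         reason = reason[reason != ""],
                         stringsAsFactors = FALSE)
  if (nrow(rejected))
    warning(sprintf("%d row(s) rejected during parsing of %s",
                    nrow(rejected), basename(path)), call. = FALSE)
  rec <- rec[reason == "", , drop = FALSE]
  if (nrow(rec) == 0L) .stopf("no valid rows in %s", path)
  ## soft consistency check: P vs two-sided normal tail of beta/se
  pImp <- .pFromZ(rec$beta / rec$se)
  inc <- which(pImp > 1e-290 & (rec$pval > 2 * pImp | rec$pval < pImp / 2))
  if (length(inc))
    warning(sprintf(
      "%d row(s) with P inconsistent with |beta/se| beyond a factor of 2",
      length(inc)), call. = FALSE)
  ss <- sumStats(if (is.null(traitId)) basename(path) else traitId,
                 traitType, rec, metadata = list(path = path))
  attr(ss, "rejected") <- rejected
  ss
}

#' Write summary statistics in the canonical TSV dialect
#'
#' Deterministic column order and fixed formatting so that identical objects
#' produce byte-identical files.
#'
#' @param x a \linkS4class{SumStats}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSumStats <- function(x, path) {
  stopifnot(is(x, "SumStats"))
  rec <- x@records
  out <- rec
  names(out) <- names(.tsvCols)[match(names(rec), .tsvCols)]
  .writeTsv(out[, names(.tsvCols)], path)
}

#' Construct an LDMatrix
#'
#' @param snpIds ordered SNP identifiers.
#' @param r square signed correlation matrix.
#' @return a validated \linkS4class{LDMatrix}.
#' @export
ldMatrix <- function(snpIds, r) {
  r <- as.matrix(r)
  dimnames(r) <- list(snpIds, snpIds)
  new("LDMatrix", snpIds = as.character(snpIds), r = r)
}

#' Read / write an LD matrix as TSV
#'
#' Format: a header row of SNP ids followed by the square numeric body.
#' @param path file path.
#' @return \code{readLDMatrix}: an \linkS4class{LDMatrix}.
#' @export
readLDMatrix <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  ldMatrix(colnames(tab), as.matrix(tab))
}

#' @rdname readLDMatrix
#' @param x an \linkS4class{LDMatrix}.
#' @export
writeLDMatrix <- function(x, path) {
  stopifnot(is(x, "LDMatrix"))
  df <- as.data.frame(x@r)
  colnames(df) <- x@snpIds
  .writeTsv(df, path)
}

#' Subset a SumStats by SNP id, preserving order of `ids`
#' @param x a \linkS4class{SumStats}.
#' @param ids SNP identifiers to keep (all must be present).
#' @return a \linkS4class{SumStats} restricted to \code{ids}.
#' @export
subsetSumStats <- function(x, ids) {
  idx <- match(ids, x@records$snp)
  if (anyNA(idx))
    .stopf("SNP(s) absent from %s: %s", x@traitId,
           paste(ids[is.na(idx)], collapse = ", "))
  rec <- x@records[idx, , drop = FALSE]
  sumStats(x@traitId, x@traitType, rec, x@metadata)
}

#' Subset an LDMatrix by SNP id
#' @param x an \linkS4class{LDMatrix}.
#' @param ids SNP identifiers to keep, in the returned order.
#' @return an \linkS4class{LDMatrix}.
#' @export
subsetLDMatrix <- function(x, ids) {
  idx <- match(ids, x@snpIds)
  if (anyNA(idx))
    .stopf("SNP(s) absent from LD matrix: %s",
           paste(ids[is.na(idx)], collapse = ", "))
  ldMatrix(ids, x@r[idx, idx, drop = FALSE])
}
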