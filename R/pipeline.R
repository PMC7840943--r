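#' @include mr-core.R coloc.R steiger.R tissue.R instruments.R simulate.R
NULL

#' Join MR, colocalisation and Steiger results into an evidence record
#'
#' Applies the robust-evidence rule: a gene-tissue-subtype association is
#' robust iff its MR P value passes at least the suggestive threshold, its
#' colocalisation tier is strong (H4 >= 0.80) and Steiger filtering returns
#' category true.  When the coloc/Steiger objects carry a \code{"keys"}
#' attribute (as the pipeline sets), it is checked against the MR result and
#' a mismatch is an error.
#'
#' @param mr an \linkS4class{MRResult}.
#' @param coloc a \linkS4class{ColocResult}.
#' @param steiger a \linkS4class{SteigerResult}.
#' @param thresholds a \linkS4class{ThresholdSet}.
#' @return one-row data.frame with columns GENE, SNPS, TISSUE, SUBTYPE, OR,
#'   CI_LOW, CI_HIGH, P, H4, COLOC_TIER, STEIGER_P, STEIGER_CATEGORY, ROBUST.
#' @export
classifyEvidence <- function(mr, coloc, steiger, thresholds) {
  stopifnot(is(mr, "MRResult"), is(coloc, "ColocResult"),
            is(steiger, "SteigerResult"), is(thresholds, "ThresholdSet"))
  key <- c(mr@geneId, mr@tissue, mr@subtype)
  for (obj in list(coloc, steiger)) {
    k <- attr(obj, "keys")
    if (!is.null(k) && !identical(unname(k), unname(key)))
      .stopf("evidence join key mismatch: MR is %s but partner is %s",
             paste(key, collapse = "/"), paste(k, collapse = "/"))
  }
  h4 <- unname(coloc@posteriors["h4"])
  tier <- classifyColoc(h4)
  robust <- (mr@pval < thresholds@suggestive) && tier == "strong" &&
    steiger@category == "true"
  data.frame(GENE = mr@geneId, SNPS = paste(mr@snpIds, collapse = ","),
             TISSUE = mr@tissue, SUBTYPE = mr@subtype, OR = mr@or,
             CI_LOW = mr@ciLow, CI_HIGH = mr@ciHigh, P = mr@pval, H4 = h4,
             COLOC_TIER = tier, STEIGER_P = steiger@pval,
             STEIGER_CATEGORY = steiger@category, ROBUST = robust,
             stringsAsFactors = FALSE)
}

#' Assemble a pipeline configuration
#'
#' @param exposures data.frame manifest with columns GENE, TISSUE, CLASS
#'   (\code{"brain"}, \code{"blood"} or \code{"tissue"} for the
#'   tissue-specific follow-up panels) and FILE (sumstats TSV path).
#' @param outcomes data.frame manifest with columns SUBTYPE and FILE.
#' @param ldPath LD matrix TSV covering every SNP used.
#' @param annotationPath gene annotation TSV (GENE, CHR, TSS, SYMBOL).
#' @param expressionPath optional per-gene-per-tissue mean-expression TSV
#'   (column GENE plus one column per tissue) for tau scoring; "" to skip.
#' @param nGenes,nTissues inputs to the multiple-testing thresholds.
#' @param clumpR2 LD clumping threshold (default 0.01).
#' @param discoveryP,lenientP instrument thresholds (5e-8, 5e-4).
#' @param priors a \linkS4class{ColocPriors}.
#' @param cisWindowBp,regionHalfWindowBp windows (1 Mbp; 500 kbp).
#' @param pEntry stepwise entry threshold for secondary signals.
#' @param caseCounts optional list(totalCases=, subtypeCases=) for case
#'   bookkeeping validation.
#' @param seed integer seed recorded in the run log.
#' @param outDir output directory for the stage TSVs.
#' @return a validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(exposures, outcomes, ldPath, annotationPath,
                           expressionPath = "", nGenes = NULL,
                           nTissues = 1L, clumpR2 = 0.01,
                           discoveryP = 5e-8, lenientP = 5e-4,
                           priors = colocPriors(), cisWindowBp = 1e6,
                           regionHalfWindowBp = 5e5, pEntry = 5e-8,
                           caseCounts = NULL, seed = 1L,
                           outDir = tempfile("mrcoloc_run_")) {
  cfg <- list(exposures = exposures, outcomes = outcomes, ldPath = ldPath,
              annotationPath = annotationPath,
              expressionPath = expressionPath,
              nGenes = if (is.null(nGenes))
                length(unique(exposures$GENE)) else nGenes,
              nTissues = nTissues, clumpR2 = clumpR2,
              discoveryP = discoveryP, lenientP = lenientP, priors = priors,
              cisWindowBp = cisWindowBp,
              regionHalfWindowBp = regionHalfWindowBp, pEntry = pEntry,
              caseCounts = caseCounts, seed = as.integer(seed),
              outDir = outDir)
  class(cfg) <- "PipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks manifest columns, that every referenced file exists, that windows
#' and thresholds are positive, and -- when case counts are supplied --
#' that the subtype case bookkeeping is consistent (reporting the number of
#' unclassified cases).
#'
#' @param cfg a \code{"PipelineConfig"} list.
#' @return the config, invisibly (with \code{cfg$unclassifiedCases} filled
#'   when case counts are present).
#' @export
validatePipelineConfig <- function(cfg) {
  need <- c("GENE", "TISSUE", "CLASS", "FILE")
  if (!all(need %in% names(cfg$exposures)))
    .stopf("exposures manifest needs columns %s", paste(need, collapse = ", "))
  if (!all(c("SUBTYPE", "FILE") %in% names(cfg$outcomes)))
    .stopf("outcomes manifest needs columns SUBTYPE, FILE")
  paths <- c(cfg$exposures$FILE, cfg$outcomes$FILE, cfg$ldPath,
             cfg$annotationPath,
             if (nzchar(cfg$expressionPath)) cfg$expressionPath)
  miss <- paths[!file.exists(paths)]
  if (length(miss)) .stopf("missing file(s): %s", paste(miss, collapse = ", "))
  if (cfg$cisWindowBp <= 0 || cfg$regionHalfWindowBp <= 0)
    .stopf("windows must be positive")
  if (!is.null(cfg$caseCounts))
    cfg$unclassifiedCases <- subtypeCaseCounts(
      cfg$caseCounts$totalCases, cfg$caseCounts$subtypeCases)$unclassified
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML mirrors \code{\link{pipelineConfig}} arguments; manifests are
#' inline lists of records.  Relative paths are resolved against the YAML
#' file's directory.
#'
#' @param path YAML file.
#' @return a \code{"PipelineConfig"}.
#' @importFrom yaml read_yaml
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(nzchar(p) & !grepl("^/", p),
                                file.path(base, p), p)
  man <- function(x) {
    df <- do.call(rbind, lapply(x, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    if ("FILE" %in% names(df)) df$FILE <- resolve(df$FILE)
    df
  }
  pr <- y$priors
  priors <- if (is.null(pr)) colocPriors() else
    colocPriors(pr$p1 %||% 1e-4, pr$p2 %||% 1e-4, pr$p12 %||% 1e-5,
                pr$priorSdQuant %||% 0.15, pr$priorSdCc %||% 0.2)
  pipelineConfig(exposures = man(y$exposures), outcomes = man(y$outcomes),
                 ldPath = resolve(y$ldPath),
                 annotationPath = resolve(y$annotationPath),
                 expressionPath = resolve(y$expressionPath %||% ""),
                 nGenes = y$nGenes, nTissues = y$nTissues %||% 1L,
                 clumpR2 = y$clumpR2 %||% 0.01,
                 discoveryP = y$discoveryP %||% 5e-8,
                 lenientP = y$lenientP %||% 5e-4, priors = priors,
                 cisWindowBp = y$cisWindowBp %||% 1e6,
                 regionHalfWindowBp = y$regionHalfWindowBp %||% 5e5,
                 pEntry = y$pEntry %||% 5e-8,
                 caseCounts = y$caseCounts, seed = y$seed %||% 1L,
                 outDir = y$outDir %||% tempfile("mrcoloc_run_"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.runLog <- function(state, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  cat(line, "\n", file = state$logPath, append = TRUE)
  message(line)
}

## Colocalisation of one exposure/outcome region pair with the
## conditional-analysis gate: conditional statistics are used only when
## stepwise selection finds more than one signal in the exposure region.
.colocForLead <- function(exPair, ouPair, lead, ld, cfg) {
  regX <- extractRegion(exPair, lead, cfg$regionHalfWindowBp)
  regY <- extractRegion(ouPair, lead, cfg$regionHalfWindowBp)
  nEff <- if (!is.null(ouPair@metadata$nEff)) ouPair@metadata$nEff
          else stats::median(ouPair@records$n)
  signals <- stepwiseSelect(regX, ld, pEntry = cfg$pEntry)
  if (length(signals) > 1L) {
    others <- setdiff(signals, lead)
    regX <- conditionalSumStats(regX, ld, others)
    regY <- conditionalSumStats(regY, ld, others, n = nEff)
  }
  colocABF(regX, regY, cfg$priors)
}

#' Run the full prioritisation pipeline
#'
#' Stage order: discovery instrument selection and MR per gene x tissue x
#' subtype; suggestive-threshold gating; for passing associations,
#' region extraction, stepwise conditional analysis, colocalisation and
#' Steiger filtering; evidence classification into the robust set; the
#' tissue-specific follow-up (lenient instruments, per-tissue MR, Cochran's
#' Q, Z-discordance, tau); and the brain-versus-blood estimate correlation.
#' Every stage writes a plain TSV into \code{cfg$outDir} and a run log
#' records seeds, thresholds and per-unit failures; a failing unit is logged
#' and skipped (fail-soft), and the returned summary counts failures.
#' Later stages read earlier stages' TSVs, so re-running a single stage from
#' cached outputs reproduces identical tables.
#'
#' @param cfg a \code{"PipelineConfig"}.
#' @param stages subset of \code{c("discovery", "coloc", "steiger",
#'   "evidence", "tissues", "correlate")}; default all, in order.
#' @return invisible list of the stage tables plus a \code{summary} with the
#'   robust-set count and the number of failed units.
#' @export
runPipeline <- function(cfg, stages = c("discovery", "coloc", "steiger",
                                        "evidence", "tissues",
                                        "correlate")) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  validatePipelineConfig(cfg)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  state <- list(logPath = file.path(cfg$outDir, "run.log"))
  thr <- multipleTestingThresholds(cfg$nGenes, cfg$nTissues)
  .runLog(state, "run start: seed %d, %d genes, thresholds %.3g / %.3g",
          cfg$seed, cfg$nGenes, thr@bonferroni, thr@suggestive)
  if (!is.null(cfg$caseCounts))
    .runLog(state, "case bookkeeping: %d cases unclassified",
            subtypeCaseCounts(cfg$caseCounts$totalCases,
                              cfg$caseCounts$subtypeCases)$unclassified)
  nFailed <- 0L
  failSoft <- function(unit, expr) {
    tryCatch(expr, error = function(e) {
      nFailed <<- nFailed + 1L
      .runLog(state, "FAILED [%s]: %s", unit, conditionMessage(e))
      NULL
    })
  }
  ld <- readLDMatrix(cfg$ldPath)
  annot <- readGeneAnnotation(cfg$annotationPath)
  outcomes <- lapply(seq_len(nrow(cfg$outcomes)), function(i)
    readSumStats(cfg$outcomes$FILE[i], "binary", cfg$outcomes$SUBTYPE[i]))
  names(outcomes) <- cfg$outcomes$SUBTYPE
  tables <- list()
  tsv <- function(name) file.path(cfg$outDir, paste0(name, ".tsv"))
  readStage <- function(name) {
    if (!is.null(tables[[name]])) return(tables[[name]])
    if (!file.exists(tsv(name)))
      .stopf("stage '%s' output not found; run it first", name)
    utils::read.delim(tsv(name), sep = "\t", stringsAsFactors = FALSE)
  }

  discoveryExposures <- cfg$exposures[cfg$exposures$CLASS %in%
                                        c("brain", "blood"), , drop = FALSE]

  ## cache of harmonised pairs and instruments keyed by unit id
  pairs <- new.env(parent = emptyenv())
  harmoniseUnit <- function(i, subtype) {
    key <- paste(i, subtype, sep = "|")
    if (!is.null(pairs[[key]])) return(pairs[[key]])
    ex <- readSumStats(discoveryExposures$FILE[i], "quantitative",
                       paste0(discoveryExposures$GENE[i], ":",
                              discoveryExposures$TISSUE[i]))
    pairs[[key]] <- harmonise(ex, outcomes[[subtype]])
    pairs[[key]]
  }

  if ("discovery" %in% stages) {
    insRows <- list(); mrRes <- list()
    for (i in seq_len(nrow(discoveryExposures))) {
      gene <- discoveryExposures$GENE[i]
      tissueLab <- discoveryExposures$TISSUE[i]
      for (subtype in names(outcomes)) {
        unit <- sprintf("%s/%s/%s", gene, tissueLab, subtype)
        failSoft(unit, {
          pair <- harmoniseUnit(i, subtype)
          instr <- selectInstruments(pair@exposure, annot[[gene]], ld,
                                     "discovery", tissue = tissueLab,
                                     windowBp = cfg$cisWindowBp,
                                     r2Threshold = cfg$clumpR2,
                                     pThreshold = cfg$discoveryP)
          if (nrow(instr@records) == 0L) {
            .runLog(state, "no instrument for %s", unit)
          } else {
            insRows[[length(insRows) + 1L]] <- data.frame(
              GENE = gene, TISSUE = tissueLab, SNP = instr@records$snp,
              BETA = instr@records$beta, SE = instr@records$se,
              P = instr@records$pval, stringsAsFactors = FALSE)
            mrRes[[length(mrRes) + 1L]] <-
              mrForInstrument(instr, pair@outcome, subtype)
          }
        })
      }
    }
    tables$instruments <- if (length(insRows)) unique(do.call(rbind, insRows))
      else data.frame(GENE = character(), TISSUE = character(),
                      SNP = character(), BETA = numeric(), SE = numeric(),
                      P = numeric())
    tables$mr <- if (length(mrRes)) mrResultsTable(mrRes)
      else data.frame(GENE = character(), SNPS = character(),
                      TISSUE = character(), SUBTYPE = character(),
                      OR = numeric(), CI_LOW = numeric(),
                      CI_HIGH = numeric(), P = numeric(),
                      METHOD = character(), N_SNP = integer())
    .writeTsv(tables$instruments, tsv("instruments"))
    .writeTsv(tables$mr, tsv("mr"))
    .runLog(state, "discovery: %d MR results (%d passing suggestive)",
            nrow(tables$mr), sum(tables$mr$P < thr@suggestive))
  }

  passingUnits <- function() {
    mr <- readStage("mr")
    mr[mr$P < thr@suggestive, , drop = FALSE]
  }

  if ("coloc" %in% stages) {
    mrPass <- passingUnits()
    rows <- list()
    for (k in seq_len(nrow(mrPass))) {
      row <- mrPass[k, ]
      i <- which(discoveryExposures$GENE == row$GENE &
                   discoveryExposures$TISSUE == row$TISSUE)[1]
      unit <- sprintf("%s/%s/%s", row$GENE, row$TISSUE, row$SUBTYPE)
      failSoft(unit, {
        pair <- harmoniseUnit(i, row$SUBTYPE)
        lead <- strsplit(row$SNPS, ",")[[1]][1]
        cr <- .colocForLead(pair@exposure, pair@outcome, lead, ld, cfg)
        h <- cr@posteriors
        rows[[length(rows) + 1L]] <- data.frame(
          GENE = row$GENE, TISSUE = row$TISSUE, SUBTYPE = row$SUBTYPE,
          NSNPS = cr@nSnps, H0 = h[1], H1 = h[2], H2 = h[3], H3 = h[4],
          H4 = h[5], TIER = classifyColoc(unname(h[5])),
          stringsAsFactors = FALSE)
      })
    }
    tables$coloc <- if (length(rows)) do.call(rbind, rows)
      else data.frame(GENE = character(), TISSUE = character(),
                      SUBTYPE = character(), NSNPS = integer(),
                      H0 = numeric(), H1 = numeric(), H2 = numeric(),
                      H3 = numeric(), H4 = numeric(), TIER = character())
    rownames(tables$coloc) <- NULL
    .writeTsv(tables$coloc, tsv("coloc"))
    .runLog(state, "coloc: %d regions (%d strong)", nrow(tables$coloc),
            sum(tables$coloc$TIER == "strong"))
  }

  if ("steiger" %in% stages) {
    mrPass <- passingUnits()
    rows <- list()
    for (k in seq_len(nrow(mrPass))) {
      row <- mrPass[k, ]
      i <- which(discoveryExposures$GENE == row$GENE &
                   discoveryExposures$TISSUE == row$TISSUE)[1]
      unit <- sprintf("%s/%s/%s", row$GENE, row$TISSUE, row$SUBTYPE)
      failSoft(unit, {
        pair <- harmoniseUnit(i, row$SUBTYPE)
        snps <- strsplit(row$SNPS, ",")[[1]]
        rec <- pair@exposure@records
        instr <- new("Instrument", geneId = row$GENE, tissue = row$TISSUE,
                     records = rec[match(snps, rec$snp), , drop = FALSE],
                     clumpR2 = cfg$clumpR2, pThreshold = cfg$discoveryP)
        st <- steigerForInstrument(instr, pair@outcome)
        rows[[length(rows) + 1L]] <- data.frame(
          GENE = row$GENE, TISSUE = row$TISSUE, SUBTYPE = row$SUBTYPE,
          R2_EXP = st@r2Exposure, R2_OUT = st@r2Outcome, Z = st@z,
          P = st@pval, CATEGORY = st@category, stringsAsFactors = FALSE)
      })
    }
    tables$steiger <- if (length(rows)) do.call(rbind, rows)
      else data.frame(GENE = character(), TISSUE = character(),
                      SUBTYPE = character(), R2_EXP = numeric(),
                      R2_OUT = numeric(), Z = numeric(), P = numeric(),
                      CATEGORY = character())
    .writeTsv(tables$steiger, tsv("steiger"))
    .runLog(state, "steiger: %d results (%d true)", nrow(tables$steiger),
            sum(tables$steiger$CATEGORY == "true"))
  }

  if ("evidence" %in% stages) {
    mrPass <- passingUnits()
    co <- readStage("coloc")
    st <- readStage("steiger")
    key <- function(d) paste(d$GENE, d$TISSUE, d$SUBTYPE, sep = "|")
    rows <- list()
    for (k in seq_len(nrow(mrPass))) {
      row <- mrPass[k, ]
      ico <- match(key(row), key(co))
      ist <- match(key(row), key(st))
      if (is.na(ico) || is.na(ist)) next
      robust <- row$P < thr@suggestive && co$TIER[ico] == "strong" &&
        st$CATEGORY[ist] == "true"
      rows[[length(rows) + 1L]] <- data.frame(
        GENE = row$GENE, SNPS = row$SNPS, TISSUE = row$TISSUE,
        SUBTYPE = row$SUBTYPE, OR = row$OR, CI_LOW = row$CI_LOW,
        CI_HIGH = row$CI_HIGH, P = row$P, H4 = co$H4[ico],
        COLOC_TIER = co$TIER[ico], STEIGER_P = st$P[ist],
        STEIGER_CATEGORY = st$CATEGORY[ist], ROBUST = robust,
        stringsAsFactors = FALSE)
    }
    tables$evidence <- if (length(rows)) do.call(rbind, rows)
      else data.frame(GENE = character(), SNPS = character(),
                      TISSUE = character(), SUBTYPE = character(),
                      OR = numeric(), CI_LOW = numeric(),
                      CI_HIGH = numeric(), P = numeric(), H4 = numeric(),
                      COLOC_TIER = character(), STEIGER_P = numeric(),
                      STEIGER_CATEGORY = character(), ROBUST = logical())
    .writeTsv(tables$evidence, tsv("evidence"))
    .runLog(state, "evidence: %d records, %d robust",
            nrow(tables$evidence), sum(tables$evidence$ROBUST))
  }

  if ("tissues" %in% stages) {
    tisExp <- cfg$exposures[cfg$exposures$CLASS == "tissue", , drop = FALSE]
    if (nrow(tisExp) == 0L) {
      .runLog(state, "tissues: no tissue-class exposures; stage skipped")
    } else {
      ev <- readStage("evidence")
      genes <- unique(ev$GENE[ev$ROBUST])
      mrRows <- list(); hetRows <- list()
      for (gene in genes) {
        sub <- tisExp[tisExp$GENE == gene, , drop = FALSE]
        for (subtype in names(outcomes)) {
          perTissue <- list()
          for (j in seq_len(nrow(sub))) {
            unit <- sprintf("%s/%s/%s", gene, sub$TISSUE[j], subtype)
            failSoft(unit, {
              ex <- readSumStats(sub$FILE[j], "quantitative",
                                 paste0(gene, ":", sub$TISSUE[j]))
              pair <- harmonise(ex, outcomes[[subtype]])
              instr <- selectInstruments(pair@exposure, annot[[gene]], ld,
                                         "tissue_specific",
                                         tissue = sub$TISSUE[j],
                                         windowBp = cfg$cisWindowBp,
                                         r2Threshold = cfg$clumpR2,
                                         pThreshold = cfg$lenientP)
              if (nrow(instr@records))
                perTissue[[sub$TISSUE[j]]] <-
                  mrForInstrument(instr, pair@outcome, subtype)
            })
          }
          if (length(perTissue))
            mrRows[[length(mrRows) + 1L]] <- mrResultsTable(perTissue)
          if (length(perTissue) >= 2L) {
            b <- vapply(perTissue, slot, numeric(1), "beta")
            s <- vapply(perTissue, slot, numeric(1), "se")
            q <- cochranQ(b, s)
            disc <- if (length(perTissue) >= 3L)
              tissueZDiscordance(names(perTissue), b, s) else character()
            hetRows[[length(hetRows) + 1L]] <- data.frame(
              GENE = gene, SUBTYPE = subtype, Q = q$q, DF = q$df,
              P = q$pval,
              DISCORDANT_TISSUES = paste(disc, collapse = ","),
              stringsAsFactors = FALSE)
          }
        }
      }
      tables$tissue_mr <- if (length(mrRows)) do.call(rbind, mrRows)
        else NULL
      tables$heterogeneity <- if (length(hetRows)) do.call(rbind, hetRows)
        else NULL
      if (!is.null(tables$tissue_mr))
        .writeTsv(tables$tissue_mr, tsv("tissue_mr"))
      if (!is.null(tables$heterogeneity))
        .writeTsv(tables$heterogeneity, tsv("heterogeneity"))
      ## tau scores from the expression table
      if (nzchar(cfg$expressionPath)) {
        expr <- utils::read.delim(cfg$expressionPath, sep = "\t",
                                  stringsAsFactors = FALSE)
        tauRows <- lapply(intersect(genes, expr$GENE), function(gene) {
          v <- as.numeric(expr[expr$GENE == gene, -1])
          ts <- tauScore(v, geneId = gene)
          data.frame(GENE = gene, TAU = ts$tau, N_TISSUES = ts$nTissues,
                     SPECIFIC = ts$specific, stringsAsFactors = FALSE)
        })
        if (length(tauRows)) {
          tables$tau <- do.call(rbind, tauRows)
          .writeTsv(tables$tau, tsv("tau"))
        }
      }
      .runLog(state, "tissues: %d genes followed up", length(genes))
    }
  }

  if ("correlate" %in% stages) {
    mr <- readStage("mr")
    pick <- function(cls) {
      keep <- mr$TISSUE %in%
        cfg$exposures$TISSUE[cfg$exposures$CLASS == cls]
      d <- mr[keep & mr$SUBTYPE == names(outcomes)[1], , drop = FALSE]
      if (!nrow(d)) return(NULL)
      data.frame(gene = d$GENE, beta = log(d$OR), pval = d$P,
                 stringsAsFactors = FALSE)
    }
    a <- pick("brain"); b <- pick("blood")
    if (is.null(a) || is.null(b)) {
      .runLog(state, "correlate: need both brain and blood results; skipped")
    } else {
      tables$correlation <- brainBloodCorrelation(a, b)
      .writeTsv(tables$correlation, tsv("correlation"))
      .runLog(state, "correlate: %d thresholds", nrow(tables$correlation))
    }
  }

  summary <- list(nFailed = nFailed,
                  nRobust = if (!is.null(tables$evidence))
                    sum(tables$evidence$ROBUST) else NA_integer_,
                  thresholds = thr, outDir = cfg$outDir)
  .runLog(state, "run end: %d unit failures", nFailed)
  tables$summary <- summary
  invisible(tables)
}

#' Generate the 20-gene synthetic truth-recovery benchmark
#'
#' Writes a complete pipeline input set to \code{dir}: per-gene exposure
#' sumstats (single "brain" tissue), one combined case-control outcome, a
#' block-diagonal LD matrix, gene annotation, a random expression table and
#' the truth sidecar.  Default composition: 8 shared_variant, 4
#' distinct_variants, 4 exposure_only, 4 null genes, each on its own 60-SNP
#' AR(1) rho = 0.8 region (blocks of 20) with the calibration sample sizes
#' (5000 exposure individuals, 5000 cases / 5000 controls).  For
#' distinct_variants genes the exposure and outcome causal SNPs sit in
#' different LD blocks (r = 0).
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param composition named integer vector of scenario counts.
#' @param nSnps,rho,blockSize per-gene LD geometry.
#' @return list with \code{config} (a ready \code{"PipelineConfig"}) and
#'   \code{truth} (data.frame of per-gene scenarios).
#' @export
simulateBenchmark <- function(dir, seed = 1L,
                              composition = c(shared_variant = 8L,
                                              distinct_variants = 4L,
                                              exposure_only = 4L,
                                              null = 4L),
                              nSnps = 60L, rho = 0.8, blockSize = 20L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scenNames <- rep(names(composition), composition)
  nGenes <- length(scenNames)
  expRows <- list(); outRecs <- list(); annRows <- list()
  ldIds <- character(); ldBlocks <- list()
  truthRows <- list()
  for (g in seq_len(nGenes)) {
    geneId <- sprintf("GENE%02d", g)
    prefix <- sprintf("g%02d_rs", g)
    ld <- simulateLDMatrix(nSnps, rho, blockSize, snpPrefix = prefix)
    mid <- as.integer(nSnps %/% 2)
    q1 <- max(1L, as.integer(nSnps %/% 4))
    q3 <- min(nSnps, as.integer(3L * (nSnps %/% 4)))
    scen <- switch(scenNames[g],
      shared_variant = simScenario("shared_variant",
                                   causalSnpExposure = mid),
      distinct_variants = simScenario("distinct_variants",
                                      causalSnpExposure = q1,
                                      causalSnpOutcome = q3),
      exposure_only = simScenario("exposure_only", causalSnpExposure = mid),
      null = simScenario("null"))
    posStart <- 1e6 + (g - 1) * 5e6
    pair <- simulateStudyPair(scen, ld, seed = seed * 1000L + g,
                              posStart = posStart)
    exFile <- file.path(dir, sprintf("%s_brain.tsv", geneId))
    writeSumStats(pair$exposure, exFile)
    expRows[[g]] <- data.frame(GENE = geneId, TISSUE = "brain",
                               CLASS = "brain", FILE = exFile,
                               stringsAsFactors = FALSE)
    outRecs[[g]] <- pair$outcome@records
    annRows[[g]] <- data.frame(GENE = geneId, CHR = "1",
                               TSS = posStart + (nSnps %/% 2) * 1000,
                               SYMBOL = geneId, stringsAsFactors = FALSE)
    ldIds <- c(ldIds, ld@snpIds)
    ldBlocks[[g]] <- ld@r
    truthRows[[g]] <- data.frame(GENE = geneId, SCENARIO = scenNames[g],
                                 TRUE_WALD = pair$truth@trueWaldEffect,
                                 stringsAsFactors = FALSE)
  }
  ## combined outcome over all gene regions
  outAll <- do.call(rbind, outRecs)
  outFile <- file.path(dir, "outcome_all_glioma.tsv")
  writeSumStats(sumStats("all_glioma", "binary", outAll), outFile)
  ## block-diagonal LD over every SNP
  total <- length(ldIds)
  R <- matrix(0, total, total)
  off <- 0L
  for (b in ldBlocks) {
    idx <- off + seq_len(nrow(b)); R[idx, idx] <- b; off <- off + nrow(b)
  }
  ldFile <- file.path(dir, "ld.tsv")
  writeLDMatrix(ldMatrix(ldIds, R), ldFile)
  annFile <- file.path(dir, "annotation.tsv")
  .writeTsv(do.call(rbind, annRows), annFile)
  ## random expression table over 13 pseudo-tissues for tau scoring
  set.seed(seed + 99L)
  exprTab <- data.frame(GENE = sprintf("GENE%02d", seq_len(nGenes)),
                        matrix(stats::rlnorm(nGenes * 13, 1, 1), nGenes, 13,
                               dimnames = list(NULL,
                                               sprintf("T%02d", 1:13))))
  exprFile <- file.path(dir, "expression.tsv")
  .writeTsv(exprTab, exprFile)
  truth <- do.call(rbind, truthRows)
  .writeTsv(truth, file.path(dir, "truth.tsv"))
  cfg <- pipelineConfig(
    exposures = do.call(rbind, expRows),
    outcomes = data.frame(SUBTYPE = "all_glioma", FILE = outFile,
                          stringsAsFactors = FALSE),
    ldPath = ldFile, annotationPath = annFile, expressionPath = exprFile,
    nGenes = nGenes, nTissues = 1L, seed = seed,
    outDir = file.path(dir, "out"))
  list(config = cfg, truth = truth)
}
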