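## Report orchestration: the plasmid and mRNA workflows, QC report
## assembly, serialisation and structural validation.

QC_SCHEMA_VERSION <- "1.0"

defaultReportParams <- function(params = list()) {
  defaults <- list(minQuality = 9, tolerance = 0L, minDepth = 20L,
                   minFraction = 0.5, k = 21L, minContainment = 0.5,
                   binWidth = 50L, sizeTolerance = 0.05,
                   tssWindow = 25L, tssMinFraction = 0.001, tssClusterGap = 10L,
                   psiThreshold = 0.3, psiMinDepth = 50L,
                   scanModifications = FALSE, seed = NA_integer_)
  defaults[names(params)] <- params
  defaults
}

reportInputs <- function(paths, params) {
  list(paths = paths, parameters = params, seed = params$seed,
       tool_version = as.character(packageVersion("mrnaqc")))
}

## mapping / purity accounting over primary records
mappingSection <- function(reads, filtered, triage = NULL) {
  primary <- reads[!reads$is_secondary & !reads$is_supplementary, , drop = FALSE]
  n <- nrow(primary)
  sec <- list(n_records = nrow(reads),
              n_primary = n,
              n_mapped = sum(!primary$is_unmapped),
              n_pass_filter = nrow(filtered),
              mapped_fraction = if (n) mean(!primary$is_unmapped) else 0)
  if (!is.null(triage)) {
    fr <- triage$summary$fractions * (sum(primary$is_unmapped) / max(n, 1L))
    sec$unmapped_triage_fractions <- as.list(fr)
  } else sec$unmapped_triage_fractions <- NULL
  sec
}

lengthSection <- function(lengths, expectedLength = NULL, sizeTolerance = 0.05) {
  if (!length(lengths))
    return(list(n = 0L, mean = NULL, median = NULL, size_fraction = NULL,
                expected_length = expectedLength))
  out <- list(n = length(lengths), mean = mean(lengths),
              median = as.numeric(median(lengths)),
              expected_length = expectedLength)
  out$size_fraction <- if (!is.null(expectedLength))
    sizeFraction(lengths, expectedLength, sizeTolerance) else NULL
  out
}

errorSection <- function(profile, layout = NULL, corrected = NULL) {
  sec <- list(global = profileSummary(profile))
  if (!is.null(layout)) {
    per <- lapply(seq_len(nrow(layout@regions)), function(i) {
      r <- layout@regions[i, ]
      s <- profileSummary(profile, c(start = r$start, end = r$end))
      s$region <- r$name
      s
    })
    names(per) <- layout@regions$name
    sec$per_region <- per
  }
  if (!is.null(corrected)) sec$corrected_global <- profileSummary(corrected)
  sec
}

consensusSection <- function(cons, reference) {
  refb <- as.character(reference)
  calls <- cons$calls
  covered <- calls$call != "N"
  ident <- if (any(covered))
    mean(calls$call[covered] == calls$ref[covered]) else NA_real_
  list(n_positions = nrow(calls),
       n_masked = sum(!covered),
       n_variants = nrow(cons$variants),
       identity_over_covered = ident,
       variants = if (nrow(cons$variants)) cons$variants else NULL)
}

#' Plasmid-mode QC report
#'
#' Runs the template workflow: read filtering, pileup, per-nucleotide error
#' profile, consensus + variants, read length distribution, and triage of
#' unmapped reads against the plasmid itself plus an optional contaminant
#' reference. Returns (and optionally writes) a machine-readable QC report.
#'
#' @param bam SAM/BAM path of reads aligned to the plasmid reference.
#' @param referenceFasta single-record plasmid reference FASTA.
#' @param contaminantFasta optional contaminant reference FASTA.
#' @param outDir optional output directory for `report.json` and section
#'   TSVs.
#' @param params named list overriding defaults: `minQuality` (9),
#'   `minDepth` (20), `minFraction` (0.5), `k` (21), `minContainment`
#'   (0.5), `binWidth` (50), `seed`.
#' @return a `mrnaqc_qc_report` list; `$success` is FALSE when no mapped
#'   read survives filtering (sections zeroed).
#' @export
runPlasmidReport <- function(bam, referenceFasta, contaminantFasta = NULL,
                             outDir = NULL, params = list()) {
  params <- defaultReportParams(params)
  refs <- Biostrings::readDNAStringSet(referenceFasta)
  if (length(refs) != 1L) stopf("reference FASTA must hold exactly one record")
  refseq <- refs[[1L]]
  reads <- loadAlignments(bam)
  filtered <- filterReads(reads, minQuality = params$minQuality)
  report <- list(mode = "plasmid", schema_version = QC_SCHEMA_VERSION,
                 inputs = reportInputs(list(bam = bam,
                                            reference = referenceFasta,
                                            contaminant = contaminantFasta),
                                       params),
                 success = nrow(filtered) > 0L)
  triage <- NULL
  unmapped <- reads[reads$is_unmapped, , drop = FALSE]
  if (nrow(unmapped)) {
    idx <- list(buildKmerIndex(as.character(refseq), k = params$k,
                               label = "construct"))
    if (!is.null(contaminantFasta)) {
      cont <- Biostrings::readDNAStringSet(contaminantFasta)
      idx <- c(idx, list(buildKmerIndex(as.character(cont[[1L]]),
                                        k = params$k, label = "contaminant")))
    }
    triage <- classifyUnmapped(unmapped, idx,
                               minContainment = params$minContainment)
  }
  report$mapping <- mappingSection(reads, filtered, triage)
  if (!report$success) {
    for (s in c("length", "error", "consensus", "classes", "polya",
                "antisense", "cryptic_tss", "modification"))
      report[s] <- list(NULL)
    class(report) <- "mrnaqc_qc_report"
    return(report)
  }
  pile <- buildPileup(filtered, refseq)
  prof <- errorProfile(pile, minDepth = params$minDepth)
  cons <- callConsensus(pile, minDepth = params$minDepth,
                        minFraction = params$minFraction)
  lens <- readLengths(filtered)
  report$length <- lengthSection(lens)
  report$error <- errorSection(prof)
  report$consensus <- consensusSection(cons, refseq)
  for (s in c("classes", "polya", "antisense", "cryptic_tss", "modification"))
    report[s] <- list(NULL)
  class(report) <- "mrnaqc_qc_report"
  if (!is.null(outDir))
    writeReportArtifacts(report, outDir, profile = prof, consensus = cons,
                         lengths = lens, triage = triage)
  report
}

#' mRNA-mode QC report
#'
#' Runs the full product workflow: filtering, pileup, error profile with
#' optional baseline (template) subtraction, consensus, integrity
#' classification, size fraction, poly(A) tail estimation + deletion-rate
#' correction, antisense fraction, cryptic TSS detection, unmapped triage,
#' and an optional modification-signature scan against a matched control.
#'
#' @param bam SAM/BAM path of reads aligned to the construct reference.
#' @param referenceFasta single-record reference FASTA.
#' @param regionsBed 4-column BED with construct region annotations.
#' @param contaminantFasta optional contaminant reference FASTA.
#' @param baselineProfile optional baseline error profile: a TSV written by
#'   [writeProfileTSV()] or an `mrnaqc_error_profile` data.frame.
#' @param controlBam optional matched unmodified control SAM/BAM for the
#'   modification scan.
#' @param outDir optional output directory.
#' @param params named list overriding defaults; see [runPlasmidReport()]
#'   plus `tolerance` (0), `sizeTolerance` (0.05), `tssWindow` (25),
#'   `tssMinFraction` (0.001), `tssClusterGap` (10), `psiThreshold` (0.3),
#'   `psiMinDepth` (50), `scanModifications` (FALSE).
#' @return a `mrnaqc_qc_report` list.
#' @export
runMrnaReport <- function(bam, referenceFasta, regionsBed,
                          contaminantFasta = NULL, baselineProfile = NULL,
                          controlBam = NULL, outDir = NULL, params = list()) {
  params <- defaultReportParams(params)
  layout <- loadConstruct(referenceFasta, regionsBed)
  reads <- loadAlignments(bam, layout = layout)
  filtered <- filterReads(reads, minQuality = params$minQuality)
  report <- list(mode = "mrna", schema_version = QC_SCHEMA_VERSION,
                 inputs = reportInputs(list(bam = bam,
                                            reference = referenceFasta,
                                            regions = regionsBed,
                                            contaminant = contaminantFasta,
                                            baseline_profile =
                                              if (is.character(baselineProfile))
                                                baselineProfile else NULL,
                                            control_bam = controlBam),
                                       params),
                 success = nrow(filtered) > 0L)
  triage <- NULL
  unmapped <- reads[reads$is_unmapped, , drop = FALSE]
  if (nrow(unmapped)) {
    idx <- list(buildKmerIndex(as.character(layout@sequence), k = params$k,
                               label = "construct"))
    if (!is.null(contaminantFasta)) {
      cont <- Biostrings::readDNAStringSet(contaminantFasta)
      idx <- c(idx, list(buildKmerIndex(as.character(cont[[1L]]),
                                        k = params$k, label = "contaminant")))
    }
    triage <- classifyUnmapped(unmapped, idx,
                               minContainment = params$minContainment)
  }
  report$mapping <- mappingSection(reads, filtered, triage)
  if (!report$success) {
    for (s in c("length", "error", "consensus", "classes", "polya",
                "antisense", "cryptic_tss", "modification"))
      report[s] <- list(NULL)
    class(report) <- "mrnaqc_qc_report"
    return(report)
  }

  pile <- buildPileup(filtered, layout)
  prof <- errorProfile(pile, minDepth = params$minDepth)
  corrected <- NULL
  if (!is.null(baselineProfile)) {
    base <- if (is.character(baselineProfile))
      read.table(baselineProfile, header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE) else baselineProfile
    if (nrow(base) != nrow(prof))
      stopf("baseline profile length mismatch (%d vs %d positions)",
            nrow(base), nrow(prof))
    corrected <- subtractBaseline(prof, base)
  }
  cons <- callConsensus(pile, minDepth = params$minDepth,
                        minFraction = params$minFraction)
  cl <- classifyLibrary(filtered, layout, tolerance = params$tolerance)
  lens <- readLengths(filtered)
  ti <- transcriptInterval(layout)
  report$length <- lengthSection(lens, expectedLength = intervalLength(ti),
                                 sizeTolerance = params$sizeTolerance)
  report$error <- errorSection(prof, layout, corrected)
  report$consensus <- consensusSection(cons, layout@sequence)
  report$classes <- cl$summary

  pa <- tailRegion(layout)
  est <- NULL
  if (is.null(pa)) {
    warnf("layout lacks a polya annotation; poly(A) section is null")
    report["polya"] <- list(NULL)
  } else {
    sense <- filtered[!filtered$is_reverse, , drop = FALSE]
    polyaSec <- tryCatch({
      dr <- tailDeletionRate(pile, pa, minDepth = params$minDepth)
      est <- correctTailLengths(tailLengths(sense, pa), dr)
      s <- tailSummary(est)
      c(list(expected_length = intervalLength(pa), deletion_rate = dr), s)
    }, error = function(e) {
      warnf("poly(A) estimation unavailable: %s", conditionMessage(e))
      NULL
    })
    report["polya"] <- list(polyaSec)
  }

  report$antisense <- list(fraction = antisenseFraction(filtered,
                                                        "long_single_end"))
  tssDf <- detectCrypticTSS(filtered, layout, window = params$tssWindow,
                            minFraction = params$tssMinFraction,
                            clusterGap = params$tssClusterGap)
  report$cryptic_tss <- list(n_sites = nrow(tssDf),
                             total_fraction = sum(tssDf$fraction),
                             sites = if (nrow(tssDf)) tssDf else NULL)

  if (isTRUE(params$scanModifications)) {
    ctrlPile <- NULL
    if (!is.null(controlBam)) {
      ctrl <- filterReads(loadAlignments(controlBam, layout = layout),
                          minQuality = params$minQuality)
      ctrlPile <- buildPileup(ctrl, layout)
    }
    scan <- scanPsiSignature(pile, ctrlPile, layout,
                             cFractionThreshold = params$psiThreshold,
                             minDepth = params$psiMinDepth)
    report$modification <- list(
      n_scored = nrow(scan),
      n_flagged = sum(scan$flagged),
      flagged_fraction = if (nrow(scan)) mean(scan$flagged) else NA_real_,
      mean_score = if (nrow(scan)) mean(scan$score, na.rm = TRUE) else NA_real_)
  } else report["modification"] <- list(NULL)

  class(report) <- "mrnaqc_qc_report"
  if (!is.null(outDir))
    writeReportArtifacts(report, outDir, profile = prof, corrected = corrected,
                         consensus = cons, lengths = lens, classes = cl,
                         tailEstimates = est, triage = triage)
  report
}

writeReportArtifacts <- function(report, outDir, profile = NULL,
                                 corrected = NULL, consensus = NULL,
                                 lengths = NULL, classes = NULL,
                                 tailEstimates = NULL, triage = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeQCReport(report, file.path(outDir, "report.json"))
  if (!is.null(profile))
    writeProfileTSV(profile, file.path(outDir, "error_profile.tsv"))
  if (!is.null(corrected))
    writeProfileTSV(corrected, file.path(outDir, "error_profile_corrected.tsv"))
  if (!is.null(consensus)) {
    x <- Biostrings::DNAStringSet(consensus$consensus)
    names(x) <- "consensus"
    Biostrings::writeXStringSet(x, file.path(outDir, "consensus.fa"))
    writeProfileTSV(consensus$variants, file.path(outDir, "variants.tsv"))
  }
  if (!is.null(lengths))
    writeProfileTSV(lengthHistogram(lengths),
                    file.path(outDir, "length_histogram.tsv"))
  if (!is.null(classes))
    writeProfileTSV(classes$records, file.path(outDir, "read_classes.tsv"))
  if (!is.null(tailEstimates))
    writeProfileTSV(tailEstimates, file.path(outDir, "tail_estimates.tsv"))
  if (!is.null(triage))
    writeProfileTSV(triage$labels, file.path(outDir, "triage.tsv"))
  invisible(outDir)
}

#' Serialise a QC report to JSON
#'
#' Deterministic serialisation (no timestamps; numbers at full precision),
#' so identical inputs produce byte-identical reports.
#'
#' @param report an `mrnaqc_qc_report`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeQCReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Structurally validate a QC report
#'
#' Checks the report against the shipped schema
#' (`system.file("schema", "qcreport-1.0.json", package = "mrnaqc")`):
#' mode, schema version, presence of every section key (absent analyses
#' must be explicit nulls, never missing), and that every field whose name
#' ends in `fraction` (or is a `fractions` map) lies in `[0, 1]`.
#'
#' @param report an `mrnaqc_qc_report` or a list parsed from `report.json`.
#' @return character vector of violations (empty when valid).
#' @export
validateQCReport <- function(report) {
  v <- character()
  required <- c("mode", "schema_version", "inputs", "success", "mapping",
                "length", "error", "consensus", "classes", "polya",
                "antisense", "cryptic_tss", "modification")
  missing <- setdiff(required, names(report))
  if (length(missing))
    v <- c(v, sprintf("missing section '%s'", missing))
  if (!is.null(report$mode) && !report$mode %in% c("plasmid", "mrna"))
    v <- c(v, sprintf("unknown mode '%s'", report$mode))
  if (!identical(as.character(report$schema_version %||% ""), QC_SCHEMA_VERSION))
    v <- c(v, "schema_version mismatch")
  checkFractions <- function(x, path) {
    out <- character()
    if (is.list(x)) {
      for (nm in names(x))
        out <- c(out, checkFractions(x[[nm]], paste0(path, ".", nm)))
    } else if (is.numeric(x) &&
               (grepl("fraction$", path) || grepl("fractions\\.", path))) {
      bad <- !is.na(x) & (x < 0 | x > 1)
      if (any(bad)) out <- sprintf("%s out of [0, 1]", path)
    }
    out
  }
  v <- c(v, checkFractions(unclass(report), "report"))
  v
}

#' @export
print.mrnaqc_qc_report <- function(x, ...) {
  cat(sprintf("mrnaqc %s report (schema %s): %s\n", x$mode, x$schema_version,
              if (isTRUE(x$success)) "success" else "FAILED (no usable reads)"))
  if (!is.null(x$mapping))
    cat(sprintf("  mapped fraction: %.3f over %d primary records\n",
                x$mapping$mapped_fraction, x$mapping$n_primary))
  if (!is.null(x$classes))
    cat(sprintf("  full-length fraction: %.3f\n",
                x$classes$fractions[["full_length"]]))
  if (!is.null(x$polya))
    cat(sprintf("  poly(A): mean corrected %.1f nt (expected %d)\n",
                x$polya$mean, x$polya$expected_length))
  invisible(x)
}
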