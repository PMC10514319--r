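## Alignment ingestion, filtering, and the per-position pileup that all
## downstream analytics consume.

#' Load alignment records from SAM or BAM
#'
#' Decodes every record (including unmapped ones, which are needed for
#' contamination triage) into a flat data.frame. SAM input is converted with
#' [Rsamtools::asBam()] first, so SAM and BAM twins yield identical read
#' sets. CIGAR ops `=`/`X` are accepted (folded into M downstream); `N`, `P`
#' and `H` are rejected as not meaningful for these libraries.
#'
#' @param path SAM (`.sam`) or BAM file.
#' @param layout optional [ConstructLayout-class]; when given, the header
#'   reference length must match the layout reference length.
#' @return data.frame with columns `read_id`, `flag`, `is_unmapped`,
#'   `is_secondary`, `is_supplementary`, `is_reverse`, `is_paired`,
#'   `is_first_in_pair`, `is_second_in_pair`, `ref_start` (0-based),
#'   `cigar`, `seq`, `qual`, `mean_qual` (arithmetic mean of per-base phred
#'   scores).
#' @export
loadAlignments <- function(path, layout = NULL) {
  nExpected <- NA_integer_
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    nExpected <- sum(!startsWith(readLines(path), "@"))
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai")), force = TRUE))
  } else bam <- path
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (!length(hdr)) stopf("alignment header carries no reference length")
  if (!is.null(layout)) {
    want <- length(layout@sequence)
    got <- unname(hdr[referenceId(layout)])
    if (is.na(got) || got != want)
      stopf("reference length mismatch: header %s, layout %d nt",
            ifelse(is.na(got), "lacks the layout reference", got), want)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "pos", "mapq",
                                        "cigar", "seq", "qual"))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  ## htslib silently drops records it cannot parse (e.g. CIGAR/SEQ length
  ## disagreement); for SAM input we can detect the loss
  if (!is.na(nExpected) && length(x$qname) != nExpected)
    stopf("%d of %d SAM records failed to parse (malformed CIGAR or fields)",
          nExpected - length(x$qname), nExpected)
  flag <- x$flag
  seqs <- as.character(x$seq)
  quals <- as.character(x$qual)
  mq <- rep(NA_real_, length(flag))
  ok <- !is.na(quals) & quals != "*" & nzchar(quals)
  if (any(ok))
    mq[ok] <- vapply(quals[ok], function(q) mean(utf8ToInt(q)), 0,
                     USE.NAMES = FALSE) - 33

  rd <- data.frame(read_id = x$qname,
                   flag = flag,
                   is_unmapped = bitwAnd(flag, 4L) > 0L,
                   is_secondary = bitwAnd(flag, 256L) > 0L,
                   is_supplementary = bitwAnd(flag, 2048L) > 0L,
                   is_reverse = bitwAnd(flag, 16L) > 0L,
                   is_paired = bitwAnd(flag, 1L) > 0L,
                   is_first_in_pair = bitwAnd(flag, 64L) > 0L,
                   is_second_in_pair = bitwAnd(flag, 128L) > 0L,
                   ref_start = ifelse(is.na(x$pos), NA_integer_, x$pos - 1L),
                   cigar = ifelse(is.na(x$cigar), "*", x$cigar),
                   seq = seqs,
                   qual = quals,
                   mean_qual = mq,
                   stringsAsFactors = FALSE)
  checkCigars(rd)
  rd
}

## Validate CIGARs of mapped records: known ops only, query width == |SEQ|.
checkCigars <- function(rd) {
  m <- which(!rd$is_unmapped & rd$cigar != "*")
  if (!length(m)) return(invisible(rd))
  cig <- rd$cigar[m]
  bad <- grepl("[NPH]", cig)
  if (any(bad))
    stopf("unsupported CIGAR op (N/P/H) in record '%s'", rd$read_id[m][bad][1L])
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(cig)
  ne <- qw != nchar(rd$seq[m])
  if (any(ne))
    stopf("CIGAR/SEQ length mismatch in record '%s' (CIGAR consumes %d, SEQ %d)",
          rd$read_id[m][ne][1L], qw[ne][1L], nchar(rd$seq[m])[ne][1L])
  invisible(rd)
}

#' Filter alignment records
#'
#' Retains mapped records whose mean base quality is strictly above
#' `minQuality` (the usual nanopore pass gate is Q>9), dropping secondary
#' and supplementary alignments when `primaryOnly` so each molecule is
#' counted once. Idempotent.
#'
#' @param reads data.frame from [loadAlignments()].
#' @param minQuality phred threshold (strict `>`).
#' @param primaryOnly drop secondary/supplementary records.
#' @return the filtered data.frame.
#' @export
filterReads <- function(reads, minQuality = 9, primaryOnly = TRUE) {
  keep <- !reads$is_unmapped & !is.na(reads$mean_qual) &
    reads$mean_qual > minQuality
  if (primaryOnly) keep <- keep & !reads$is_secondary & !reads$is_supplementary
  reads[keep, , drop = FALSE]
}

#' PileupProfile: per-reference-position base and indel counts
#'
#' For every reference position: counts of aligned A/C/G/T, spanning
#' deletions, and insertion events anchored immediately left of the
#' position (one count per event regardless of inserted length). Depth at a
#' position is the number of reads whose alignment consumes it
#' (`A+C+G+T+del`); soft-clipped bases contribute nothing.
#'
#' @slot referenceId reference name.
#' @slot reference the reference [Biostrings::DNAString].
#' @slot counts integer matrix, length x 5, columns `A,C,G,T,del`; row `i`
#'   is 0-based position `i - 1`.
#' @slot insertions integer vector of insertion event counts per position.
#' @seealso [buildPileup()], [pileupDepth()], [writePileupTSV()]
#' @export
setClass("PileupProfile",
  representation(referenceId = "character",
                 reference = "ANY",
                 counts = "matrix",
                 insertions = "integer"))

setValidity("PileupProfile", function(object) {
  L <- length(object@reference)
  if (nrow(object@counts) != L) return("counts rows must equal reference length")
  if (!identical(colnames(object@counts), c("A", "C", "G", "T", "del")))
    return("counts columns must be A,C,G,T,del")
  if (length(object@insertions) != L)
    return("insertions must have one entry per position")
  TRUE
})

#' @describeIn PileupProfile-class per-position depth (`A+C+G+T+del`)
#' @param x a `PileupProfile`.
#' @export
setGeneric("pileupDepth", function(x) standardGeneric("pileupDepth"))
#' @export
setMethod("pileupDepth", "PileupProfile", function(x) unname(rowSums(x@counts)))

#' @describeIn PileupProfile-class the length x 5 count matrix
#' @export
setGeneric("pileupCounts", function(x) standardGeneric("pileupCounts"))
#' @export
setMethod("pileupCounts", "PileupProfile", function(x) x@counts)

#' @describeIn PileupProfile-class insertion event counts per position
#' @export
setGeneric("insertionCounts", function(x) standardGeneric("insertionCounts"))
#' @export
setMethod("insertionCounts", "PileupProfile", function(x) x@insertions)

setMethod("show", "PileupProfile", function(object) {
  d <- pileupDepth(object)
  cat(sprintf("PileupProfile: %s, %d nt; depth mean %.1f, max %d; %d insertion events\n",
              object@referenceId, length(object@reference),
              mean(d), max(d, 0L), sum(object@insertions)))
})

#' Build a pileup from aligned reads
#'
#' Walks every mapped record's CIGAR against the reference: M/=/X bases are
#' tallied by called base, D ops are tallied as spanning deletions at each
#' deleted position, I ops are counted once per event at their left-anchor
#' position, and soft clips are skipped. Reads must already be filtered
#' (see [filterReads()]).
#'
#' @param reads data.frame of mapped records ([loadAlignments()] columns).
#' @param reference a [ConstructLayout-class], [Biostrings::DNAString] or
#'   character reference sequence.
#' @param chunkSize internal batching of reads (memory/speed trade-off).
#' @return A [PileupProfile-class].
#' @export
buildPileup <- function(reads, reference, chunkSize = 4000L) {
  if (is(reference, "ConstructLayout")) {
    refseq <- reference@sequence
    refid <- reference@referenceId
  } else {
    refseq <- if (is.character(reference)) Biostrings::DNAString(reference)
              else reference
    refid <- "ref"
  }
  L <- length(refseq)
  rd <- reads[!reads$is_unmapped, , drop = FALSE]
  checkCigars(rd)
  counts <- matrix(0L, nrow = L, ncol = 5L,
                   dimnames = list(NULL, c("A", "C", "G", "T", "del")))
  ins <- integer(L)
  n <- nrow(rd)
  if (n) {
    rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(rd$cigar)
    over <- rd$ref_start + rw > L
    if (any(over))
      stopf("read '%s' extends past reference end (%d > %d)",
            rd$read_id[over][1L], (rd$ref_start + rw)[over][1L], L)
    for (lo in seq(1L, n, by = chunkSize)) {
      idx <- lo:min(lo + chunkSize - 1L, n)
      acc <- pileupChunk(rd[idx, , drop = FALSE], L)
      counts <- counts + acc$counts
      ins <- ins + acc$ins
    }
  }
  new("PileupProfile", referenceId = refid, reference = refseq,
      counts = counts, insertions = ins)
}

## Vectorised tally for one chunk of reads.
pileupChunk <- function(rd, L) {
  cig <- rd$cigar
  pos1 <- rd$ref_start + 1L
  mOps <- c("M", "=", "X")
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(cig, pos = pos1, ops = mOps)
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = mOps)
  nper <- S4Vectors::elementNROWS(rr)
  urr <- unlist(rr, use.names = FALSE)
  uqr <- unlist(qr, use.names = FALSE)
  w <- IRanges::width(urr)
  readOfRange <- rep(seq_len(nrow(rd)), nper)
  refposFlat <- sequence(w, from = IRanges::start(urr))
  qposLocal <- sequence(w, from = IRanges::start(uqr))
  off <- cumsum(nchar(rd$seq)) - nchar(rd$seq)
  qposFlat <- qposLocal + rep(off[readOfRange], w)
  codes <- BASE_CODE[utf8ToInt(paste(rd$seq, collapse = ""))][qposFlat]
  keep <- !is.na(codes)
  tallied <- tabulate((codes[keep] - 1L) * L + refposFlat[keep], nbins = 4L * L)
  counts <- matrix(0L, nrow = L, ncol = 5L,
                   dimnames = list(NULL, c("A", "C", "G", "T", "del")))
  counts[, 1:4] <- tallied
  ## deletions: one count per spanned position
  dr <- unlist(GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = pos1, ops = "D"), use.names = FALSE)
  if (length(dr)) {
    dpos <- sequence(IRanges::width(dr), from = IRanges::start(dr))
    counts[, 5L] <- tabulate(dpos, nbins = L)
  }
  ## insertions: one count per event at the left-anchor position
  ir <- unlist(GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = pos1, ops = "I"), use.names = FALSE)
  ins <- integer(L)
  if (length(ir)) {
    anchor <- pmax(IRanges::start(ir) - 1L, 1L)
    ins <- tabulate(anchor, nbins = L)
  }
  list(counts = counts, ins = ins)
}

#' Serialise a pileup to TSV
#'
#' One row per reference position: `position` (0-based), `ref`, `A`, `C`,
#' `G`, `T`, `del`, `ins`, `depth`.
#'
#' @param pileup a [PileupProfile-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writePileupTSV <- function(pileup, path) {
  df <- data.frame(position = seq_len(nrow(pileup@counts)) - 1L,
                   ref = strsplit(as.character(pileup@reference), "",
                                  fixed = TRUE)[[1]],
                   pileup@counts,
                   ins = pileup@insertions,
                   depth = pileupDepth(pileup))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
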