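## Integrity analytics: full-length vs truncated classification, read
## length distributions, cryptic transcription start site detection.

#' Classify reads as full-length or truncated
#'
#' With target interval `T = [kozak.start, utr3.end)` and tolerance `t`:
#' a read is `full_length` iff it covers both ends
#' (`aln_start <= T.start + t` and `aln_end >= T.end - t`); `trunc5` iff it
#' reaches the 3' end but not the 5' end (RNase degradation proxy);
#' `trunc3` iff it reaches the 5' end but not the 3' end (abortive
#' transcription proxy); `trunc_both` otherwise. Deterministic and
#' order-invariant; every mapped read receives exactly one class.
#'
#' @param reads data.frame of mapped, primary records (an unmapped record is
#'   an error — route those to contamination triage instead).
#' @param layout a [ConstructLayout-class].
#' @param tolerance nt of slop at each target boundary (default 0: strict
#'   coordinate overlap; 5-10 nt can be warranted when adaptor trimming
#'   leaves ragged ends).
#' @return data.frame with `read_id`, `cls`, `orientation`
#'   (`sense`/`antisense`), `aln_start`, `aln_end` (0-based half-open).
#' @export
classifyReads <- function(reads, layout, tolerance = 0L) {
  if (any(reads$is_unmapped))
    stopf("classifyReads received %d unmapped read(s); route them to contamination triage",
          sum(reads$is_unmapped))
  tg <- targetInterval(layout)
  aStart <- reads$ref_start
  aEnd <- reads$ref_start +
    GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  cover5 <- aStart <= tg[["start"]] + tolerance
  cover3 <- aEnd >= tg[["end"]] - tolerance
  cls <- ifelse(cover5 & cover3, "full_length",
         ifelse(!cover5 & cover3, "trunc5",
         ifelse(cover5 & !cover3, "trunc3", "trunc_both")))
  data.frame(read_id = reads$read_id, cls = cls,
             orientation = ifelse(reads$is_reverse, "antisense", "sense"),
             aln_start = aStart, aln_end = aEnd, stringsAsFactors = FALSE)
}

#' Classify a whole library and summarise integrity
#'
#' Classifies every mapped primary read, then summarises: the truncation
#' partition (fractions over classified sense reads), the antisense
#' fraction, and the upstream/downstream off-target fractions (sense reads
#' lying wholly 5' of the transcript start or wholly 3' of the poly(A) end;
#' such reads are reported separately and excluded from the truncation
#' partition, which is about the mRNA product itself).
#'
#' @param reads data.frame of filtered records ([filterReads()]).
#' @param layout a [ConstructLayout-class].
#' @param tolerance see [classifyReads()].
#' @return list with `records` (per-read class data.frame) and `summary`
#'   (list: `n_reads`, `n_classified`, per-class `counts` and `fractions`,
#'   `antisense_fraction`, `upstream_fraction`, `downstream_fraction`,
#'   `on_target_fraction`).
#' @export
classifyLibrary <- function(reads, layout, tolerance = 0L) {
  rec <- classifyReads(reads, layout, tolerance = tolerance)
  ti <- transcriptInterval(layout)
  pa <- tailRegion(layout)
  sense <- rec$orientation == "sense"
  upstream <- sense & rec$aln_end <= ti[["start"]]
  downstream <- if (!is.null(pa)) sense & rec$aln_start >= pa[["end"]]
                else rep(FALSE, nrow(rec))
  offTarget <- upstream | downstream
  classified <- sense & !offTarget
  n <- nrow(rec)
  cls <- factor(rec$cls[classified],
                levels = c("full_length", "trunc5", "trunc3", "trunc_both"))
  counts <- table(cls)
  fr <- if (sum(counts)) as.numeric(counts) / sum(counts) else rep(NA_real_, 4L)
  summary <- list(
    n_reads = n,
    n_classified = sum(classified),
    counts = setNames(as.integer(counts), names(counts)),
    fractions = setNames(fr, names(counts)),
    antisense_fraction = if (n) mean(!sense) else NA_real_,
    upstream_fraction = if (n) mean(upstream) else NA_real_,
    downstream_fraction = if (n) mean(downstream) else NA_real_,
    on_target_fraction = if (n) mean(classified) else NA_real_)
  list(records = rec, summary = summary)
}

#' Read length distribution
#'
#' Per-read query lengths, soft clips included, so degraded-but-unaligned
#' tails still count toward molecule size.
#'
#' @param reads data.frame of records.
#' @return integer vector of read lengths named by read id.
#' @export
readLengths <- function(reads) {
  setNames(nchar(reads$seq), reads$read_id)
}

#' Histogram of read lengths
#'
#' @param lengths integer vector from [readLengths()].
#' @param binWidth histogram bin width (nt).
#' @return data.frame `bin_start`, `bin_end`, `count`; counts sum to the
#'   read count.
#' @export
lengthHistogram <- function(lengths, binWidth = 50L) {
  b <- (lengths %/% binWidth) * binWidth
  tab <- table(b)
  data.frame(bin_start = as.integer(names(tab)),
             bin_end = as.integer(names(tab)) + as.integer(binWidth),
             count = as.integer(tab))
}

#' Fraction of reads near the expected length
#'
#' The operational analogue of integrating the primary electrophoretic
#' peak: the fraction of reads whose length is within
#' `relTolerance * expectedLength` of the expected length.
#'
#' @param lengths integer vector of read lengths.
#' @param expectedLength expected transcript length (nt), > 0.
#' @param relTolerance symmetric relative window (default 0.05).
#' @return proportion in `[0, 1]`.
#' @export
sizeFraction <- function(lengths, expectedLength, relTolerance = 0.05) {
  stopifnot(expectedLength > 0)
  mean(abs(lengths - expectedLength) <= relTolerance * expectedLength)
}

#' Detect cryptic transcription start sites
#'
#' Builds the histogram of 5' alignment starts of sense reads; positions
#' outside `[TSS - window, TSS + window]` whose count reaches
#' `minFraction` of all sense reads are merged into clusters separated by
#' more than `clusterGap` nt, each reported at its modal position.
#'
#' @param reads data.frame of mapped primary records.
#' @param layout a [ConstructLayout-class].
#' @param window nt around the annotated TSS treated as expected starts.
#' @param minFraction minimum per-position start fraction to seed a site.
#' @param clusterGap positions closer than this merge into one cluster.
#' @return data.frame `position` (cluster mode, 0-based), `count`,
#'   `fraction`; zero rows when no candidate site exists.
#' @export
detectCrypticTSS <- function(reads, layout, window = 25L,
                             minFraction = 0.001, clusterGap = 10L) {
  sense <- reads[!reads$is_reverse & !reads$is_unmapped, , drop = FALSE]
  empty <- data.frame(position = integer(), count = integer(),
                      fraction = numeric())
  total <- nrow(sense)
  if (!total) return(empty)
  tss <- transcriptInterval(layout)[["start"]]
  starts <- sense$ref_start
  outside <- starts < tss - window | starts > tss + window
  tab <- table(starts[outside])
  pos <- as.integer(names(tab))
  cnt <- as.integer(tab)
  seed <- cnt >= minFraction * total
  if (!any(seed)) return(empty)
  pos <- pos[seed]; cnt <- cnt[seed]
  o <- order(pos); pos <- pos[o]; cnt <- cnt[o]
  clusterId <- cumsum(c(1L, diff(pos) > clusterGap))
  out <- do.call(rbind, lapply(split(seq_along(pos), clusterId), function(i) {
    mode <- pos[i][which.max(cnt[i])]
    data.frame(position = mode, count = sum(cnt[i]),
               fraction = sum(cnt[i]) / total)
  }))
  rownames(out) <- NULL
  out
}
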