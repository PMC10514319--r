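## Alignment-space poly(A) tail length estimation and homopolymer
## deletion-rate correction.

#' Raw poly(A) tail length per read
#'
#' For each mapped sense read, the raw tail length is the number of read
#' bases consumed by M and I ops whose reference anchor lies within the
#' tail region (insertions anchor at the base to their left; inserted bases
#' are real called bases and count). Optionally a 3'-terminal soft-clipped
#' A-run (an enzymatic or overshooting tail) is added. `spans_tail_end`
#' records whether the alignment reaches the 3' end of the tail region:
#' reads that stop short carry censored tails.
#'
#' @param reads data.frame of mapped, primary, sense records (an antisense
#'   record is an error).
#' @param tailRegion named `c(start, end)` 0-based half-open, e.g.
#'   [tailRegion()] of the layout.
#' @param includeTrailingSoftclip also count the leading A-run of a
#'   3'-terminal soft clip.
#' @return data.frame `read_id`, `raw_length`, `spans_tail_end`.
#' @export
tailLengths <- function(reads, tailRegion, includeTrailingSoftclip = FALSE) {
  if (any(reads$is_unmapped)) stopf("tailLengths requires mapped reads")
  if (any(reads$is_reverse))
    stopf("tailLengths received antisense read(s): tail estimation assumes the 3'-anchored sense orientation")
  ts <- tailRegion[["start"]]; te <- tailRegion[["end"]]
  n <- nrow(reads)
  cig <- reads$cigar
  pos1 <- reads$ref_start + 1L
  raw <- integer(n)
  if (n) {
    mOps <- c("M", "=", "X")
    rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(cig, pos = pos1,
                                                            ops = mOps)
    urr <- unlist(rr, use.names = FALSE)
    readOf <- rep(seq_len(n), S4Vectors::elementNROWS(rr))
    ## overlap of each M range with the tail region (1-based [ts+1, te])
    ov <- pmax(0L, pmin(IRanges::end(urr), te) -
                    pmax(IRanges::start(urr), ts + 1L) + 1L)
    agg <- rowsum(ov, readOf)
    raw[as.integer(rownames(agg))] <- as.integer(agg)
    ## insertions whose left anchor (0-based) lies in [ts, te)
    ir <- GenomicAlignments::cigarRangesAlongReferenceSpace(cig, pos = pos1,
                                                            ops = "I")
    iq <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = "I")
    uir <- unlist(ir, use.names = FALSE)
    if (length(uir)) {
      iReadOf <- rep(seq_len(n), S4Vectors::elementNROWS(ir))
      anchor0 <- IRanges::start(uir) - 2L     # 1-based start-1, to 0-based
      wI <- IRanges::width(unlist(iq, use.names = FALSE))
      inTail <- anchor0 >= ts & anchor0 < te
      if (any(inTail)) {
        add <- rowsum(wI[inTail], iReadOf[inTail])
        raw[as.integer(rownames(add))] <- raw[as.integer(rownames(add))] +
          as.integer(add)
      }
    }
    if (includeTrailingSoftclip) {
      hasSc <- grepl("\\d+S$", cig)
      scLen <- integer(n)
      scLen[hasSc] <- as.integer(sub("S$", "",
        regmatches(cig, regexpr("\\d+S$", cig))))
      for (i in which(scLen > 0L)) {
        clip <- substr(reads$seq[i], nchar(reads$seq[i]) - scLen[i] + 1L,
                       nchar(reads$seq[i]))
        run <- regmatches(clip, regexpr("^A+", clip))
        if (length(run)) raw[i] <- raw[i] + nchar(run)
      }
    }
  }
  aEnd <- reads$ref_start +
    GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  data.frame(read_id = reads$read_id, raw_length = raw,
             spans_tail_end = aEnd >= te, stringsAsFactors = FALSE)
}

#' Aggregate deletion rate over the tail region
#'
#' `sum(deletions) / sum(depth)` over the tail positions of a pileup — the
#' quantity that drives the systematic underestimation of homopolymer tail
#' length in alignment space.
#'
#' @param pileup a [PileupProfile-class].
#' @param tailRegion named `c(start, end)` 0-based half-open.
#' @param minDepth required depth over at least half of the region.
#' @return deletion rate in `[0, 1]`.
#' @export
tailDeletionRate <- function(pileup, tailRegion, minDepth = 20L) {
  ts <- tailRegion[["start"]]; te <- tailRegion[["end"]]
  idx <- (ts + 1L):te
  depth <- pileupDepth(pileup)[idx]
  low <- depth < minDepth
  if (mean(low) > 0.5)
    stopf("insufficient depth over the tail region: %d of %d positions below %d (e.g. around position %d)",
          sum(low), length(idx), minDepth, idx[which(low)[1L]] - 1L)
  dels <- pileup@counts[idx, "del"]
  sum(dels) / sum(depth)
}

#' Correct tail lengths for homopolymer deletions
#'
#' Deletion errors shorten the apparent tail by a factor `(1 - d)` on
#' average; the corrected length rescales the raw length by
#' `1 / (1 - d)` using a single region-wide deletion rate (see
#' [tailDeletionRate()]). Only reads spanning the tail end are corrected;
#' reads with censored tails keep `corrected_length = NA` and are excluded
#' from summaries.
#'
#' @param estimates data.frame from [tailLengths()].
#' @param delRate region-wide deletion rate, `0 <= delRate < 1`.
#' @return the input with a `corrected_length` column added.
#' @export
correctTailLengths <- function(estimates, delRate) {
  if (delRate < 0 || delRate >= 1) stopf("delRate must lie in [0, 1)")
  est <- estimates
  est$corrected_length <- ifelse(est$spans_tail_end,
                                 est$raw_length / (1 - delRate), NA_real_)
  est
}

#' Summarise corrected tail lengths
#'
#' Mean, median, sd and 5/95 percentiles of the corrected tail length over
#' reads spanning the tail end; censored reads are counted as excluded.
#'
#' @param estimates data.frame from [correctTailLengths()].
#' @return named list: `mean`, `median`, `sd`, `p5`, `p95`, `n_used`,
#'   `n_excluded`, plus `mean_raw` over the same reads.
#' @export
tailSummary <- function(estimates) {
  if (!nrow(estimates)) stopf("no tail estimates")
  if (is.null(estimates$corrected_length))
    stopf("estimates lack corrected_length; run correctTailLengths() first")
  use <- estimates$spans_tail_end & !is.na(estimates$corrected_length)
  if (!any(use)) stopf("no estimate spans the tail end")
  x <- estimates$corrected_length[use]
  list(mean = mean(x), median = median(x), sd = sd(x),
       p5 = unname(quantile(x, 0.05)), p95 = unname(quantile(x, 0.95)),
       n_used = sum(use), n_excluded = sum(!use),
       mean_raw = mean(estimates$raw_length[use]))
}
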