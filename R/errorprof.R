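## Per-nucleotide error profiling, baseline subtraction, consensus calling.

#' Per-nucleotide error profile
#'
#' For every reference position with depth >= `minDepth`:
#' mismatch rate `m = (depth - del - refbase)/depth`, deletion rate
#' `d = del/depth`, insertion rate `s = ins_events/depth`, and total
#' `e = m + d + s`. Positions below `minDepth` are retained but flagged
#' undefined (`defined = FALSE`, rates NA). Note the denominator is the
#' spanning depth (aligned + deleted reads); insertion events appear only in
#' the numerator of `s`, which can therefore exceed 1 in pathological cases.
#'
#' @param pileup a [PileupProfile-class].
#' @param minDepth minimum depth for a position to be profiled.
#' @return data.frame of class `mrnaqc_error_profile` with columns
#'   `position` (0-based), `ref`, `mismatch`, `deletion`, `insertion`,
#'   `total`, `depth`, `defined`.
#' @export
errorProfile <- function(pileup, minDepth = 20L) {
  stopifnot(is(pileup, "PileupProfile"))
  cn <- pileup@counts
  L <- nrow(cn)
  refb <- strsplit(as.character(pileup@reference), "", fixed = TRUE)[[1]]
  refcode <- match(refb, BASES)                 # NA for N etc.
  depth <- rowSums(cn)
  nref <- numeric(L)
  ok <- !is.na(refcode)
  nref[ok] <- cn[cbind(which(ok), refcode[ok])]
  del <- cn[, "del"]
  m <- ifelse(depth > 0, (depth - del - nref) / depth, NA_real_)
  d <- ifelse(depth > 0, del / depth, NA_real_)
  s <- ifelse(depth > 0, pileup@insertions / depth, NA_real_)
  defined <- depth >= minDepth
  m[!defined] <- NA_real_; d[!defined] <- NA_real_; s[!defined] <- NA_real_
  out <- data.frame(position = seq_len(L) - 1L, ref = refb,
                    mismatch = m, deletion = d, insertion = s,
                    total = m + d + s, depth = depth, defined = defined,
                    stringsAsFactors = FALSE)
  class(out) <- c("mrnaqc_error_profile", "data.frame")
  out
}

#' Subtract a baseline error profile
#'
#' Removes systematic (template- or platform-borne) error from a sample
#' profile by subtracting a baseline profile (e.g. from plasmid template
#' sequencing) position by position and rate type by rate type, flooring at
#' zero. The total is recomputed from the corrected components. A position
#' is defined in the result only where both inputs are defined.
#'
#' @param sample,baseline `mrnaqc_error_profile` data.frames over the same
#'   reference length.
#' @return corrected `mrnaqc_error_profile`.
#' @export
subtractBaseline <- function(sample, baseline) {
  if (nrow(sample) != nrow(baseline))
    stopf("profile length mismatch (%d vs %d positions)",
          nrow(sample), nrow(baseline))
  out <- sample
  def <- sample$defined & baseline$defined
  for (col in c("mismatch", "deletion", "insertion")) {
    v <- pmax(0, sample[[col]] - baseline[[col]])
    v[!def] <- NA_real_
    out[[col]] <- v
  }
  out$total <- out$mismatch + out$deletion + out$insertion
  out$defined <- def
  out
}

#' Pileup-majority consensus and variant listing
#'
#' Per position, the consensus is the most frequent of
#' \{A, C, G, T, deletion\} when its fraction of the spanning depth reaches
#' `minFraction` and the depth reaches `minDepth`; otherwise the position is
#' masked with `N`. Zero-coverage positions are always masked. A deletion
#' consensus omits the base from the collapsed sequence. Ties at the top
#' fraction resolve to the reference base if it is among the tied alleles,
#' else to the first of A < C < G < T < del; tied positions are flagged.
#'
#' @param pileup a [PileupProfile-class].
#' @param minDepth minimum depth to call.
#' @param minFraction minimum top-allele fraction to call.
#' @return list with `calls` (per-position data.frame: `position`, `ref`,
#'   `call` one of A/C/G/T/-/N, `fraction`, `depth`, `tie`), `consensus`
#'   (collapsed character sequence, deletions omitted, masked positions N)
#'   and `variants` (positions where the call differs from the reference,
#'   with allele fractions).
#' @export
callConsensus <- function(pileup, minDepth = 20L, minFraction = 0.5) {
  stopifnot(is(pileup, "PileupProfile"))
  cn <- pileup@counts
  L <- nrow(cn)
  refb <- strsplit(as.character(pileup@reference), "", fixed = TRUE)[[1]]
  refcode <- match(refb, BASES)
  depth <- rowSums(cn)
  alleles <- c("A", "C", "G", "T", "-")
  mx <- do.call(pmax, as.data.frame(cn))
  first <- max.col(cn, ties.method = "first")
  nties <- rowSums(cn == mx & depth > 0)
  tie <- nties > 1L & depth > 0
  ## prefer the reference allele when it attains the maximum
  refAtMax <- !is.na(refcode) & cn[cbind(seq_len(L), refcode)] == mx
  pick <- ifelse(tie & refAtMax, refcode, first)
  frac <- ifelse(depth > 0, mx / depth, NA_real_)
  call <- alleles[pick]
  masked <- depth < minDepth | depth == 0L | is.na(frac) | frac < minFraction
  call[masked] <- "N"
  calls <- data.frame(position = seq_len(L) - 1L, ref = refb, call = call,
                      fraction = frac, depth = depth, tie = tie & !masked,
                      stringsAsFactors = FALSE)
  consensus <- paste(ifelse(call == "-", "", call), collapse = "")
  isVar <- !masked & call != refb & call != "N"
  variants <- calls[isVar, c("position", "ref", "call", "fraction", "depth")]
  names(variants)[3] <- "alt"
  rownames(variants) <- NULL
  list(calls = calls, consensus = consensus, variants = variants)
}

#' Write an error profile or variant table to TSV
#'
#' @param x data.frame (error profile, variants, ...).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeProfileTSV <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarise an error profile
#'
#' Mean per-position rates over defined positions, optionally restricted to
#' an interval (e.g. the transcript or the poly(A) tail).
#'
#' @param profile an `mrnaqc_error_profile`.
#' @param interval optional `c(start, end)` 0-based half-open restriction.
#' @return named list: mean mismatch/deletion/insertion/total rates and the
#'   number of positions used.
#' @export
profileSummary <- function(profile, interval = NULL) {
  p <- profile
  if (!is.null(interval))
    p <- p[p$position >= interval[["start"]] & p$position < interval[["end"]], ]
  p <- p[p$defined, , drop = FALSE]
  list(mismatch = mean(p$mismatch), deletion = mean(p$deletion),
       insertion = mean(p$insertion), total = mean(p$total),
       n_positions = nrow(p))
}
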