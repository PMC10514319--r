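## N1-methylpseudouridine detection from basecalling-error signatures.
##
## Nanopore basecallers systematically miscall N1-methylpseudouridine as
## cytosine; at modified positions the called-base composition shifts
## toward C (reported aggregates near 0.62 C / 0.38 U) and the error rate
## rises. These analytics score that signature per reference-U position.

#' Called-base composition per position
#'
#' Fractions of called A/C/G/T (excluding deletions) at each requested
#' position, plus the deletion fraction of the spanning depth. Positions
#' with zero called depth are flagged.
#'
#' @param pileup a [PileupProfile-class].
#' @param positions 0-based positions (default: all).
#' @return data.frame `position`, `ref`, `f_A`, `f_C`, `f_G`, `f_T`,
#'   `called_depth`, `depth`, `del_fraction`, `zero_called`.
#' @export
positionComposition <- function(pileup, positions = NULL) {
  cn <- pileup@counts
  L <- nrow(cn)
  if (is.null(positions)) positions <- seq_len(L) - 1L
  if (any(positions < 0L | positions >= L)) stopf("position out of reference")
  i <- positions + 1L
  refb <- strsplit(as.character(pileup@reference), "", fixed = TRUE)[[1]][i]
  called <- rowSums(cn[i, 1:4, drop = FALSE])
  depth <- called + cn[i, "del"]
  f <- cn[i, 1:4, drop = FALSE] / ifelse(called > 0, called, NA_real_)
  data.frame(position = positions, ref = refb,
             f_A = f[, "A"], f_C = f[, "C"], f_G = f[, "G"], f_T = f[, "T"],
             called_depth = called, depth = depth,
             del_fraction = ifelse(depth > 0, cn[i, "del"] / depth, NA_real_),
             zero_called = called == 0L,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Scan for the pseudouridine miscall signature
#'
#' For every reference-T position inside the transcript with depth >=
#' `minDepth`, the signature score is `f_C / (f_C + f_T)` — conditioning on
#' C/T calls insulates the score from the deletion-rate differences that
#' accompany modification. A position is flagged when the score reaches
#' `cFractionThreshold` and, if a matched unmodified control pileup is
#' given, its score exceeds the control score by at least half the
#' threshold (the differential mode is preferred when a matched run
#' exists). Flagged positions are a subset of reference-T positions by
#' construction, and raising the threshold never enlarges the flagged set.
#'
#' @param samplePileup a [PileupProfile-class] of the (possibly modified)
#'   sample.
#' @param controlPileup optional matched unmodified control pileup over the
#'   same reference.
#' @param layout a [ConstructLayout-class] (defines the transcript span).
#' @param cFractionThreshold absolute score threshold (default 0.3, between
#'   the unmodified mismatch baseline and the typical 0.62 signature).
#' @param minDepth minimum spanning depth to score a position.
#' @return data.frame over scored positions: `position`, `score`,
#'   `control_score`, `control_delta`, `depth`, `mismatch`, `deletion`,
#'   `insertion`, `flagged`.
#' @export
scanPsiSignature <- function(samplePileup, controlPileup = NULL, layout,
                             cFractionThreshold = 0.3, minDepth = 50L) {
  stopifnot(is(samplePileup, "PileupProfile"))
  if (!is.null(controlPileup) &&
      length(controlPileup@reference) != length(samplePileup@reference))
    stopf("control reference length differs from sample")
  ti <- transcriptInterval(layout)
  refb <- strsplit(as.character(samplePileup@reference), "", fixed = TRUE)[[1]]
  tpos0 <- which(refb == "T") - 1L
  tpos0 <- tpos0[tpos0 >= ti[["start"]] & tpos0 < ti[["end"]]]
  comp <- positionComposition(samplePileup, tpos0)
  keep <- comp$depth >= minDepth & !comp$zero_called
  comp <- comp[keep, , drop = FALSE]
  if (!nrow(comp))
    return(data.frame(position = integer(), score = numeric(),
                      control_score = numeric(), control_delta = numeric(),
                      depth = integer(), mismatch = numeric(),
                      deletion = numeric(), insertion = numeric(),
                      flagged = logical()))
  score <- comp$f_C / (comp$f_C + comp$f_T)
  ctrl <- rep(NA_real_, nrow(comp))
  if (!is.null(controlPileup)) {
    cc <- positionComposition(controlPileup, comp$position)
    ctrl <- cc$f_C / (cc$f_C + cc$f_T)
  }
  ## per-type error rates at the scored positions
  i <- comp$position + 1L
  cn <- samplePileup@counts
  depth <- rowSums(cn[i, , drop = FALSE])
  mism <- (depth - cn[i, "del"] - cn[i, "T"]) / depth
  dele <- cn[i, "del"] / depth
  inse <- samplePileup@insertions[i] / depth
  delta <- score - ctrl
  flagged <- !is.na(score) & score >= cFractionThreshold &
    (is.null(controlPileup) | (!is.na(delta) & delta >= cFractionThreshold / 2))
  data.frame(position = comp$position, score = score,
             control_score = ctrl, control_delta = delta,
             depth = as.integer(depth), mismatch = mism, deletion = dele,
             insertion = inse, flagged = as.logical(flagged),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cumulative error distributions: U vs non-U positions
#'
#' Empirical CDFs of per-position total error, partitioned by reference
#' base T (uridine in the transcript) versus A/C/G. A modified sample shows
#' the T curve shifted right (stochastically dominated by the other curve).
#'
#' @param profile an `mrnaqc_error_profile` (see [errorProfile()]).
#' @param layout optional [ConstructLayout-class]; when given, only
#'   transcript positions are used.
#' @return data.frame `group` (`"U"`/`"other"`), `error`, `cum_fraction`,
#'   sorted by error within group.
#' @export
errorCdfByBase <- function(profile, layout = NULL) {
  p <- profile[profile$defined & !is.na(profile$total), , drop = FALSE]
  if (!is.null(layout)) {
    ti <- transcriptInterval(layout)
    p <- p[p$position >= ti[["start"]] & p$position < ti[["end"]], , drop = FALSE]
  }
  grp <- ifelse(p$ref == "T", "U", "other")
  out <- do.call(rbind, lapply(split(p$total, grp), function(e) {
    e <- sort(e)
    data.frame(error = e, cum_fraction = seq_along(e) / length(e))
  }))
  out <- data.frame(group = sub("\\..*$", "", rownames(out)), out,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}
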