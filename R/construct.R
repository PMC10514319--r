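## Construct model: reference sequence + ordered, named region annotations.

#' Region labels recognised in construct annotations
#'
#' The fixed vocabulary used in the name column of the 4-column BED file that
#' annotates a construct: `promoter`, `utr5`, `kozak`, `cds`, `utr3`,
#' `linker`, `polya`, `restriction_site`, `backbone`.
#'
#' @export
REGION_NAMES <- c("promoter", "utr5", "kozak", "cds", "utr3", "linker",
                  "polya", "restriction_site", "backbone")

## Regions that belong to the transcribed mRNA, in required 5'->3' order.
TRANSCRIPT_ORDER <- c("utr5", "kozak", "cds", "utr3", "linker", "polya")

#' ConstructLayout: an annotated vaccine construct
#'
#' Holds the reference sequence of an mRNA construct (typically the plasmid
#' template or the transcribed portion of it) together with its named region
#' annotations. All coordinates are 0-based half-open.
#'
#' Derived intervals:
#' \describe{
#'   \item{transcript interval}{`[promoter.end, polya.end)` — the transcribed
#'     mRNA, with the transcription start site (TSS) taken as the first base
#'     after the promoter. If no promoter is annotated the TSS falls back to
#'     the start of the 5'-most transcript region.}
#'   \item{target interval}{`[kozak.start, utr3.end)` — the span a read must
#'     cover to count as a full-length, translatable molecule. If no `kozak`
#'     row is present, `cds.start` is used (the Kozak may alias the CDS
#'     start).}
#' }
#'
#' @slot referenceId single reference (chromosome) name.
#' @slot sequence a [Biostrings::DNAString] with the reference sequence.
#' @slot regions data.frame with columns `name`, `start`, `end` (0-based
#'   half-open).
#' @slot polyaPurity minimum fraction of A required of the annotated poly(A)
#'   region (default 0.9; the segmented tail designs keep short non-A linkers
#'   outside the annotated tail, but variants with internal linkers need
#'   slack).
#'
#' @seealso [loadConstruct()], [validateLayout()], [syntheticConstruct()]
#' @export
setClass("ConstructLayout",
  representation(
    referenceId = "character",
    sequence    = "ANY",       # DNAString
    regions     = "data.frame",
    polyaPurity = "numeric"
  ),
  prototype(polyaPurity = 0.9)
)

setValidity("ConstructLayout", function(object) {
  msg <- character()
  if (length(object@referenceId) != 1L) msg <- c(msg, "referenceId must be length 1")
  if (!is(object@sequence, "DNAString")) msg <- c(msg, "sequence must be a DNAString")
  r <- object@regions
  if (!all(c("name", "start", "end") %in% names(r)))
    msg <- c(msg, "regions must have columns name, start, end")
  if (length(msg)) msg else TRUE
})

#' Construct a ConstructLayout
#'
#' Low-level constructor; see [loadConstruct()] for building one from
#' FASTA + BED files. Structural validity is enforced here; the geometric
#' invariants are checked by [validateLayout()] (violations are data, not
#' exceptions, so that a malformed layout can be inspected).
#'
#' @param referenceId reference name.
#' @param sequence DNAString or character DNA sequence.
#' @param regions data.frame with `name`, `start`, `end` (0-based half-open).
#' @param polyaPurity minimum A fraction of the poly(A) region.
#' @return A [ConstructLayout-class] object.
#' @export
ConstructLayout <- function(referenceId, sequence, regions, polyaPurity = 0.9) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  regions <- data.frame(name = as.character(regions$name),
                        start = as.integer(regions$start),
                        end = as.integer(regions$end),
                        stringsAsFactors = FALSE)
  regions <- regions[order(regions$start, regions$end), , drop = FALSE]
  rownames(regions) <- NULL
  new("ConstructLayout", referenceId = referenceId, sequence = sequence,
      regions = regions, polyaPurity = polyaPurity)
}

#' @describeIn ConstructLayout-class reference name
#' @param x,object a `ConstructLayout`.
#' @export
setGeneric("referenceId", function(x) standardGeneric("referenceId"))
#' @export
setMethod("referenceId", "ConstructLayout", function(x) x@referenceId)

#' @describeIn ConstructLayout-class reference sequence as a DNAString
#' @export
setGeneric("referenceSequence", function(x) standardGeneric("referenceSequence"))
#' @export
setMethod("referenceSequence", "ConstructLayout", function(x) x@sequence)

#' @describeIn ConstructLayout-class region annotation table (0-based half-open)
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @export
setMethod("regions", "ConstructLayout", function(x) x@regions)

#' Look up one annotated region
#'
#' @param layout a [ConstructLayout-class].
#' @param name region name (one of [REGION_NAMES]).
#' @return named integer `c(start, end)` (0-based half-open), or `NULL` if the
#'   region is not annotated.
#' @export
region <- function(layout, name) {
  r <- layout@regions
  i <- which(r$name == name)
  if (!length(i)) return(NULL)
  c(start = r$start[i[1L]], end = r$end[i[1L]])
}

#' Transcript and target intervals of a layout
#'
#' `transcriptInterval()` is `[TSS, polya.end)` with the TSS at the first
#' transcribed base (promoter end). `targetInterval()` is
#' `[kozak.start, utr3.end)`, the span used for integrity classification.
#' `tailRegion()` is the annotated poly(A) region.
#'
#' @param layout a [ConstructLayout-class].
#' @return named integer `c(start, end)`, 0-based half-open.
#' @export
transcriptInterval <- function(layout) {
  pro <- region(layout, "promoter")
  pa  <- region(layout, "polya")
  if (is.null(pa)) stopf("layout has no polya region")
  present <- layout@regions[layout@regions$name %in% TRANSCRIPT_ORDER, ]
  tss <- if (!is.null(pro)) pro[["end"]] else min(present$start)
  c(start = as.integer(tss), end = pa[["end"]])
}

#' @rdname transcriptInterval
#' @export
targetInterval <- function(layout) {
  k <- region(layout, "kozak")
  if (is.null(k)) k <- region(layout, "cds")
  u3 <- region(layout, "utr3")
  if (is.null(k) || is.null(u3)) stopf("layout needs kozak/cds and utr3 regions")
  c(start = k[["start"]], end = u3[["end"]])
}

#' @rdname transcriptInterval
#' @export
tailRegion <- function(layout) region(layout, "polya")

#' Expected (template-encoded) poly(A) tail length
#'
#' Width of the annotated poly(A) region, in nucleotides.
#'
#' @param layout a [ConstructLayout-class].
#' @return integer tail length (nt).
#' @export
expectedTailLength <- function(layout) {
  pa <- region(layout, "polya")
  if (is.null(pa)) stopf("layout has no polya region")
  intervalLength(pa)
}

setMethod("show", "ConstructLayout", function(object) {
  cat("ConstructLayout:", object@referenceId,
      sprintf("(%d nt)\n", length(object@sequence)))
  r <- object@regions
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-16s [%6d, %6d)  %d nt\n", r$name[i], r$start[i], r$end[i],
                r$end[i] - r$start[i]))
  pa <- region(object, "polya")
  if (!is.null(pa))
    cat(sprintf("  expected tail length: %d nt\n", intervalLength(pa)))
})

#' Validate the geometry of a construct layout
#'
#' Checks every layout invariant and returns the violations as a character
#' vector of messages (empty when the layout is well formed). Violations are
#' data, not exceptions, so a malformed layout can be examined.
#'
#' Invariants checked: region bounds within the reference; unique, known
#' region names; transcript regions in 5'->3' order
#' (utr5 <= kozak <= cds <= utr3 <= linker <= polya by start); poly(A) region
#' of the reference at least `polyaPurity` adenosine; target interval nested
#' in the transcript interval.
#'
#' @param layout a [ConstructLayout-class].
#' @return character vector of violation messages (empty if valid).
#' @export
validateLayout <- function(layout) {
  v <- character()
  len <- length(layout@sequence)
  r <- layout@regions
  if (!nrow(r)) return("layout has no regions")
  bad <- !(r$name %in% REGION_NAMES)
  if (any(bad)) v <- c(v, sprintf("unknown region name '%s'", r$name[bad]))
  if (anyDuplicated(r$name))
    v <- c(v, sprintf("duplicated region name '%s'",
                      unique(r$name[duplicated(r$name)])))
  oob <- r$start < 0L | r$end > len | r$start >= r$end
  if (any(oob))
    v <- c(v, sprintf("region '%s' out of bounds: [%d, %d) on %d nt reference",
                      r$name[oob], r$start[oob], r$end[oob], len))
  present <- intersect(TRANSCRIPT_ORDER, r$name)
  if (length(present) > 1L) {
    starts <- r$start[match(present, r$name)]
    if (is.unsorted(starts))
      v <- c(v, sprintf("transcript regions out of 5'->3' order: %s",
                        paste(present, collapse = " < ")))
  }
  pa <- region(layout, "polya")
  if (is.null(pa)) {
    v <- c(v, "no polya region annotated")
  } else if (all(!oob)) {
    tailseq <- as.character(Biostrings::subseq(layout@sequence,
                                               pa[["start"]] + 1L, pa[["end"]]))
    frac_a <- mean(strsplit(tailseq, "", fixed = TRUE)[[1]] == "A")
    if (frac_a < layout@polyaPurity)
      v <- c(v, sprintf("polya region purity < %.2g (observed %.2f)",
                        layout@polyaPurity, frac_a))
    ## target nested in transcript (needs both derivable)
    ti <- tryCatch(transcriptInterval(layout), error = function(e) NULL)
    tg <- tryCatch(targetInterval(layout), error = function(e) NULL)
    if (!is.null(ti) && !is.null(tg) &&
        (tg[["start"]] < ti[["start"]] || tg[["end"]] > ti[["end"]]))
      v <- c(v, "target interval not nested in transcript interval")
  }
  v
}

#' Load a construct from FASTA + BED
#'
#' Reads a single-record reference FASTA and a 4-column BED file (name in
#' column 4, names drawn from [REGION_NAMES]) and returns a validated
#' [ConstructLayout-class]. The load is rejected if the FASTA holds more than
#' one record, a region name is unknown, a region exceeds the sequence, or
#' any other layout invariant is violated.
#'
#' @param fastaPath path to the reference FASTA (exactly one record).
#' @param bedPath path to the 4-column BED with region annotations.
#' @param polyaPurity minimum A fraction of the poly(A) region (default 0.9).
#' @return A validated [ConstructLayout-class].
#' @examples
#' lay <- syntheticConstruct()
#' td <- tempdir()
#' writeConstruct(lay, file.path(td, "ref.fa"), file.path(td, "ref.bed"))
#' lay2 <- loadConstruct(file.path(td, "ref.fa"), file.path(td, "ref.bed"))
#' targetInterval(lay2)
#' @export
loadConstruct <- function(fastaPath, bedPath, polyaPurity = 0.9) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  if (length(seqs) != 1L)
    stopf("reference FASTA must hold exactly one record (found %d)", length(seqs))
  refid <- sub("\\s.*$", "", names(seqs)[1L])
  gr <- rtracklayer::import(bedPath, format = "BED")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm) || any(is.na(nm)))
    stopf("BED file must carry region names in column 4")
  regions <- data.frame(name = as.character(nm),
                        start = GenomicRanges::start(gr) - 1L,  # back to 0-based
                        end = GenomicRanges::end(gr),
                        stringsAsFactors = FALSE)
  layout <- ConstructLayout(refid, seqs[[1L]], regions, polyaPurity = polyaPurity)
  viol <- validateLayout(layout)
  if (length(viol)) stopf("invalid construct layout:\n  %s",
                          paste(viol, collapse = "\n  "))
  layout
}

#' Write a construct back to FASTA + BED
#'
#' Inverse of [loadConstruct()]; the round trip is lossless.
#'
#' @param layout a [ConstructLayout-class].
#' @param fastaPath,bedPath output paths.
#' @return invisibly, the layout.
#' @export
writeConstruct <- function(layout, fastaPath, bedPath) {
  seqs <- Biostrings::DNAStringSet(layout@sequence)
  names(seqs) <- layout@referenceId
  Biostrings::writeXStringSet(seqs, fastaPath)
  r <- layout@regions
  ## BED is already the native coordinate convention of the layout
  writeLines(sprintf("%s\t%d\t%d\t%s", layout@referenceId, r$start, r$end,
                     r$name), bedPath)
  invisible(layout)
}

#' Find the poly(A) region of a sequence
#'
#' Convenience for references whose BED lacks a `polya` row: returns the
#' longest run of at least `minRun` consecutive A (ties resolved to the
#' 3'-most run), or `NULL` when no qualifying run exists.
#'
#' @param sequence DNAString or character DNA sequence (non-empty).
#' @param minRun minimum run length, >= 10.
#' @return named integer `c(start, end)` (0-based half-open) or `NULL`.
#' @export
detectPolyARegion <- function(sequence, minRun = 10L) {
  if (minRun < 10L) stopf("minRun must be >= 10")
  s <- as.character(sequence)
  if (!nchar(s)) stopf("empty sequence")
  runs <- rle(strsplit(toupper(s), "", fixed = TRUE)[[1]] == "A")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths         # 0-based starts
  ok <- runs$values & runs$lengths >= minRun
  if (!any(ok)) return(NULL)
  best <- which(ok & runs$lengths == max(runs$lengths[ok]))
  i <- best[length(best)]               # 3'-most on ties
  c(start = starts[i], end = ends[i])
}

#' Synthetic eGFP-style reference construct
#'
#' Builds a deterministic reference construct emulating a typical reporter
#' mRNA vaccine template: a 20 nt T7 promoter, a 47 nt 5' UTR, a 10 nt Kozak
#' region, a 720 nt coding sequence, a 245 nt 3' UTR, a 5 nt linker, a 126 nt
#' poly(A) tail, a 6 nt restriction site used for linearisation, and a
#' plasmid backbone remainder. The transcribed portion is 1153 nt.
#'
#' @param backboneLength nt of backbone sequence after the restriction site.
#' @param seed RNG seed for the random portions (fixed default so the same
#'   construct is produced every time).
#' @return A validated [ConstructLayout-class].
#' @examples
#' lay <- syntheticConstruct()
#' expectedTailLength(lay)  # 126
#' @export
syntheticConstruct <- function(backboneLength = 1000L, seed = 42L) {
  withSeed(seed, {
    promoter <- "TAATACGACTCACTATAAGG"      # modified T7 promoter, 20 nt
    utr5   <- randomDNA(47)
    kozak  <- "GCCACCATGG"
    cds    <- paste0("TG", randomDNA(712), "TAATAA")   # continues the ATG in kozak
    ## cds region is the 720 nt beginning at the ATG: place ATG at kozak[7..9]
    utr3   <- randomDNA(245)
    linker <- "GCATC"
    polya  <- strrep("A", 126)
    rsite  <- "GGTCTC"                     # BsaI recognition site
    backbone <- randomDNA(backboneLength)
    seq <- paste0(promoter, utr5, kozak, cds, utr3, linker, polya, rsite, backbone)
    regions <- data.frame(
      name  = c("promoter", "utr5", "kozak", "cds", "utr3", "linker",
                "polya", "restriction_site", "backbone"),
      start = c(0L, 20L, 67L, 77L, 797L, 1042L, 1047L, 1173L, 1179L),
      end   = c(20L, 67L, 77L, 797L, 1042L, 1047L, 1173L, 1179L,
                1179L + backboneLength))
    layout <- ConstructLayout("construct1", seq, regions)
    viol <- validateLayout(layout)
    if (length(viol)) stopf("internal error: synthetic construct invalid: %s",
                            paste(viol, collapse = "; "))
    layout
  })
}

#' Synthetic contaminant reference
#'
#' A deterministic random DNA sequence standing in for a host-genome
#' contaminant reference (e.g. residual expression-host DNA) in simulations
#' and triage tests.
#'
#' @param length sequence length (nt).
#' @param seed RNG seed.
#' @param gc GC content.
#' @return character DNA string.
#' @export
syntheticContaminant <- function(length = 5000L, seed = 99L, gc = 0.5) {
  withSeed(seed, randomDNA(length, gc = gc))
}
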