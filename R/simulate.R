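## Synthetic read simulator with an exact truth channel.
##
## Reads are generated in reference space (so the CIGAR of every construct
## read is known exactly), then emitted as FASTQ plus truth alignments (SAM)
## and a truth table. Leading/trailing deletions are kept in the CIGAR: the
## truth is known, and trimming them would censor reads whose terminal tail
## base was deleted and bias edge deletion rates.

#' Per-nucleotide sequencing error model
#'
#' Independent per-base substitution, insertion and deletion probabilities,
#' with a separate deletion rate inside the annotated poly(A) tail
#' (homopolymer deletions are strongly enriched there). Defaults reflect
#' typical nanopore direct-RNA error composition: 2.61% mismatch, 5.18%
#' deletion, 1.43% insertion, and 13% deletion within the tail.
#'
#' @param mismatch,insertion,deletion per-base probabilities, each in
#'   `[0, 0.5)`, summing to < 1.
#' @param tailDeletion deletion probability applied inside the poly(A)
#'   region (overrides `deletion` there).
#' @return an `mrnaqc_error_model` list.
#' @export
errorModel <- function(mismatch = 0.0261, insertion = 0.0143,
                       deletion = 0.0518, tailDeletion = 0.13) {
  rates <- c(mismatch = mismatch, insertion = insertion, deletion = deletion,
             tailDeletion = tailDeletion)
  if (any(rates < 0) || any(rates >= 0.5))
    stopf("error rates must lie in [0, 0.5)")
  if (mismatch + insertion + deletion >= 1)
    stopf("error rates must sum to < 1")
  structure(as.list(rates), class = "mrnaqc_error_model")
}

#' Simulation configuration
#'
#' Describes one simulated library: how many reads, the mix of transcript
#' species, the tail-length distribution and the error model. All randomness
#' is governed by `seed`; identical configurations produce byte-identical
#' FASTQ/SAM output.
#'
#' Species are drawn per read: first contaminant / antisense / cryptic-TSS /
#' readthrough according to their proportions, with the remaining mass split
#' between the four integrity classes according to `classFractions`
#' (`full_length`, `trunc5`, `trunc3`, `trunc_both`). With all extra
#' proportions at 0 (the default) the class counts are a plain multinomial
#' draw from `classFractions`.
#'
#' @param nReads number of reads.
#' @param classFractions named numeric over `full_length`, `trunc5`,
#'   `trunc3`, `trunc_both`; must sum to 1. Defaults mirror a typical IVT
#'   product: 58.2% full length, 31.3% 5' truncated, 7% 3' truncated, 3.5%
#'   doubly truncated.
#' @param antisenseFraction proportion of reverse-complement (antisense)
#'   construct fragments.
#' @param contaminantFraction proportion of reads drawn from the contaminant
#'   reference (emitted unmapped in the truth alignments).
#' @param crypticTssSites optional data.frame with columns `position`
#'   (0-based) and `weight` (per-read probability) of spurious initiation
#'   sites.
#' @param readthroughFraction proportion of reads running past the poly(A)
#'   tail into the backbone (incomplete template linearisation).
#' @param tailLengthMean true tail length mean; `NA` uses the layout's
#'   expected (template-encoded) tail length.
#' @param tailLengthSd 0 for a point mass, otherwise a (rounded, truncated
#'   at 0) normal.
#' @param polyadenylateAll emulate an extra enzymatic polyadenylation of all
#'   RNA 3' termini before library prep: every species, including truncated
#'   and antisense reads, receives a fresh 3' tail (geometric, mean
#'   `extraTailMean`), carried as soft-clipped bases in the truth alignment,
#'   and tail-less species are captured at full efficiency (see
#'   `nonPolyaCaptureRate`).
#' @param extraTailMean mean of the enzymatic tail (nt).
#' @param nonPolyaCaptureRate capture efficiency of species lacking an
#'   encoded tail (antisense, readthrough, contaminant) under 3'-anchored
#'   library prep when `polyadenylateAll` is off. Default 1 (no selection);
#'   values < 1 emulate oligo-dT selection against tail-less RNA, which the
#'   extra polyadenylation step rescues.
#' @param errorModel an [errorModel()].
#' @param baseQuality constant per-base phred quality written to FASTQ/SAM
#'   (default Q12, above the usual Q>9 pass gate).
#' @param modified simulate N1-methylpseudouridine miscalls: at reference-T
#'   transcript positions a called base becomes C with a per-position
#'   probability drawn once per run from N(`modCFraction`, `modCSd`),
#'   truncated to `[0, 1]`.
#' @param modCFraction,modCSd aggregate C-miscall fraction and its
#'   per-position spread.
#' @param seed integer RNG seed.
#' @return an `mrnaqc_sim_config` list.
#' @export
simulationConfig <- function(nReads = 1000L,
                             classFractions = c(full_length = 0.582,
                                                trunc5 = 0.313,
                                                trunc3 = 0.070,
                                                trunc_both = 0.035),
                             antisenseFraction = 0,
                             contaminantFraction = 0,
                             crypticTssSites = NULL,
                             readthroughFraction = 0,
                             tailLengthMean = NA,
                             tailLengthSd = 0,
                             polyadenylateAll = FALSE,
                             extraTailMean = 30,
                             nonPolyaCaptureRate = 1,
                             errorModel = mrnaqc::errorModel(),
                             baseQuality = 12L,
                             modified = FALSE,
                             modCFraction = 0.62,
                             modCSd = 0.05,
                             seed = 1L) {
  cls <- c("full_length", "trunc5", "trunc3", "trunc_both")
  if (!all(cls %in% names(classFractions)))
    stopf("classFractions must be named over %s", paste(cls, collapse = ", "))
  classFractions <- classFractions[cls]
  if (abs(sum(classFractions) - 1) > 1e-9)
    stopf("classFractions must sum to 1 (got %.6f)", sum(classFractions))
  props <- c(antisenseFraction, contaminantFraction, readthroughFraction)
  if (any(props < 0 | props > 1) || any(classFractions < 0))
    stopf("all proportions must lie in [0, 1]")
  if (!is.null(crypticTssSites)) {
    stopifnot(is.data.frame(crypticTssSites),
              all(c("position", "weight") %in% names(crypticTssSites)))
    if (sum(crypticTssSites$weight) > 1) stopf("cryptic TSS weights sum > 1")
  }
  structure(list(nReads = as.integer(nReads),
                 classFractions = classFractions,
                 antisenseFraction = antisenseFraction,
                 contaminantFraction = contaminantFraction,
                 crypticTssSites = crypticTssSites,
                 readthroughFraction = readthroughFraction,
                 tailLengthMean = tailLengthMean,
                 tailLengthSd = tailLengthSd,
                 polyadenylateAll = isTRUE(polyadenylateAll),
                 extraTailMean = extraTailMean,
                 nonPolyaCaptureRate = nonPolyaCaptureRate,
                 errorModel = errorModel,
                 baseQuality = as.integer(baseQuality),
                 modified = isTRUE(modified),
                 modCFraction = modCFraction,
                 modCSd = modCSd,
                 seed = as.integer(seed)),
            class = "mrnaqc_sim_config")
}

#' Apply a per-base error model to a sequence
#'
#' Draws substitutions, insertions and deletions per base from the current
#' RNG stream and returns the edited sequence together with an edit walk (a
#' run-length list over ops M/I/D) that exactly reconstructs the edit. The
#' walk is in reference orientation; M covers both matches and mismatches.
#'
#' @param sequence character or DNAString input (reference orientation).
#' @param model an [errorModel()].
#' @param tailMask optional logical vector (length `nchar(sequence)`) marking
#'   positions where `tailDeletion` replaces `deletion`.
#' @param psiProb optional numeric vector of per-position C-miscall
#'   probabilities (NA/0 where inactive), applied to retained bases.
#' @return list with `seq` (edited character sequence), `cigar` (character,
#'   e.g. `"55M1D20M"`), and `counts` (named integer: mismatch, insertion,
#'   deletion, match).
#' @export
applyErrorModel <- function(sequence, model, tailMask = NULL, psiProb = NULL) {
  s <- as.character(sequence)
  L <- nchar(s)
  if (L == 0L) stopf("empty sequence")
  zero <- model$mismatch == 0 && model$insertion == 0 && model$deletion == 0 &&
    (is.null(tailMask) || !any(tailMask) || model$tailDeletion == 0) &&
    (is.null(psiProb) || !any(psiProb > 0, na.rm = TRUE))
  if (zero) {
    return(list(seq = s, cigar = sprintf("%dM", L),
                counts = c(mismatch = 0L, insertion = 0L, deletion = 0L,
                           match = L)))
  }
  bases <- strsplit(s, "", fixed = TRUE)[[1]]
  dvec <- rep(model$deletion, L)
  if (!is.null(tailMask)) dvec[tailMask] <- model$tailDeletion
  deleted <- runif(L) < dvec
  kept <- !deleted
  ## substitutions on retained bases
  sub <- kept & (runif(L) < model$mismatch)
  if (any(sub)) {
    alt <- vapply(bases[sub], function(b) sample(setdiff(BASES, b), 1L), "")
    bases[sub] <- alt
  }
  ## modified-nucleoside miscall: retained positions forced to C
  if (!is.null(psiProb)) {
    p <- ifelse(is.na(psiProb), 0, psiProb)
    psi <- kept & (runif(L) < p) & bases != "C"
    bases[psi] <- "C"
    sub <- sub | psi
  }
  sub <- sub & kept
  ## one inserted base after position i with prob insertion
  insAfter <- runif(L) < model$insertion
  nIns <- sum(insAfter)
  insBase <- if (nIns) sample(BASES, nIns, replace = TRUE) else character()
  ## interleave ops / bases by reference position (insertion keyed after i)
  keyCore <- seq_len(L)
  keyIns <- which(insAfter) + 0.5
  ord <- order(c(keyCore, keyIns))
  opAll <- c(ifelse(deleted, "D", "M"), rep("I", nIns))[ord]
  baseAll <- c(ifelse(deleted, "", bases), insBase)[ord]
  r <- rle(opAll)
  cigar <- paste0(r$lengths, r$values, collapse = "")
  list(seq = paste(baseAll, collapse = ""),
       cigar = cigar,
       counts = c(mismatch = as.integer(sum(sub)),
                  insertion = as.integer(nIns),
                  deletion = as.integer(sum(deleted)),
                  match = as.integer(sum(kept) - sum(sub))))
}

## draw a true tail length for one tail-bearing read
drawTailLength <- function(cfg, expected) {
  m <- if (is.na(cfg$tailLengthMean)) expected else cfg$tailLengthMean
  if (cfg$tailLengthSd <= 0) return(as.integer(m))
  max(0L, as.integer(round(rnorm(1L, m, cfg$tailLengthSd))))
}

#' Simulate a sequencing library with known truth
#'
#' Generates `nReads` reads from a construct layout (and optionally a
#' contaminant reference) according to a [simulationConfig()]. Each read
#' carries an edit-exact truth record: its species, true reference interval,
#' strand, true tail length, origin, CIGAR and realised edit counts.
#'
#' Species geometry (0-based half-open; TSS = transcript start):
#' * `full_length`: spans TSS to the end of the encoded tail.
#' * `trunc5`: 5' start uniform inside `(kozak.start, utr3.start)`, reaches
#'   the tail end (degradation proxy).
#' * `trunc3`: starts at the TSS, 3' end uniform inside
#'   `(cds.start, utr3.end)`, no tail (abortive transcription proxy).
#' * `trunc_both`: truncated at both ends.
#' * `antisense`: reverse-complement fragment uniform along the transcript.
#' * `cryptic_tss`: initiates at a planted site, runs to the tail end.
#' * `readthrough`: runs past the tail into the backbone.
#' * `contaminant`: fragment of the contaminant reference; unmapped in the
#'   truth alignments.
#'
#' The template-encoded tail occupies the annotated poly(A) region, subject
#' to the tail deletion rate; true tail length beyond the encoded length
#' (and any enzymatic `polyadenylateAll` tail) is carried as soft-clipped
#' bases.
#'
#' @param layout a [ConstructLayout-class].
#' @param config a [simulationConfig()].
#' @param contaminant character/DNAString contaminant reference; required
#'   when `contaminantFraction > 0`.
#' @return list of class `mrnaqc_simulation` with elements `reads`
#'   (data.frame: read_id, seq in read orientation, qual, flag fields,
#'   ref_start, cigar in reference orientation), `truth` (the truth table),
#'   `layout`, `config`.
#' @examples
#' lay <- syntheticConstruct()
#' sim <- simulateReads(lay, simulationConfig(nReads = 50, seed = 7))
#' table(sim$truth$true_class)
#' @export
simulateReads <- function(layout, config, contaminant = NULL) {
  stopifnot(is(layout, "ConstructLayout"),
            inherits(config, "mrnaqc_sim_config"))
  if (config$contaminantFraction > 0 && is.null(contaminant))
    stopf("contaminantFraction > 0 requires a contaminant sequence")
  contaminant <- if (!is.null(contaminant)) as.character(contaminant)
  refseq <- as.character(layout@sequence)
  refLen <- nchar(refseq)
  ti <- transcriptInterval(layout)
  tg <- targetInterval(layout)
  pa <- tailRegion(layout)
  if (is.null(pa)) stopf("layout has no polya region")
  cdsI <- region(layout, "cds")
  u3 <- region(layout, "utr3")
  expected <- intervalLength(pa)
  if (!is.null(config$crypticTssSites) &&
      any(config$crypticTssSites$position >= pa[["start"]] |
          config$crypticTssSites$position < 0))
    stopf("cryptic TSS sites must lie in [0, polya.start)")
  em <- config$errorModel

  withSeed(config$seed, {
    n <- config$nReads
    ## species draw
    cw <- if (is.null(config$crypticTssSites)) 0 else sum(config$crypticTssSites$weight)
    cap <- if (config$polyadenylateAll) 1 else config$nonPolyaCaptureRate
    pSpecies <- c(contaminant = config$contaminantFraction * cap,
                  antisense = config$antisenseFraction * cap,
                  cryptic_tss = cw,
                  readthrough = config$readthroughFraction * cap)
    if (sum(pSpecies) > 1) stopf("species proportions sum > 1")
    pClasses <- config$classFractions * (1 - sum(pSpecies))
    species <- sample(c(names(pSpecies), names(pClasses)), n, replace = TRUE,
                      prob = c(pSpecies, pClasses))

    ## per-position modified-U miscall probabilities (reference space)
    psiRef <- NULL
    if (config$modified) {
      psiRef <- rep(NA_real_, refLen)
      tpos <- which(strsplit(refseq, "", fixed = TRUE)[[1]] == "T")
      tpos <- tpos[tpos > ti[["start"]] & tpos <= ti[["end"]]]  # 1-based in transcript
      psiRef[tpos] <- pmin(1, pmax(0, rnorm(length(tpos), config$modCFraction,
                                            config$modCSd)))
    }

    ids <- sprintf("read%06d", seq_len(n))
    qualChar <- intToUtf8(config$baseQuality + 33L)

    seqs <- character(n); quals <- character(n); cigars <- character(n)
    refStart <- integer(n); refEnd <- integer(n)
    strand <- rep("+", n); src <- rep("construct", n)
    tailLen <- integer(n)
    nmm <- integer(n); nins <- integer(n); ndel <- integer(n)

    tailMaskFull <- rep(FALSE, refLen)
    tailMaskFull[(pa[["start"]] + 1L):pa[["end"]]] <- TRUE

    for (i in seq_len(n)) {
      sp <- species[i]
      hasTail <- sp %in% c("full_length", "trunc5", "cryptic_tss")
      Ttail <- 0L
      if (sp == "contaminant") {
        cl <- nchar(contaminant)
        fl <- sample(100:min(1000L, cl - 1L), 1L)
        fs <- sample.int(cl - fl, 1L) - 1L            # 0-based
        s0 <- fs; e0 <- fs + fl
        src[i] <- "contaminant"
      } else if (sp == "antisense") {
        minLen <- 50L
        s0 <- sample(ti[["start"]]:(ti[["end"]] - minLen - 1L), 1L)
        e0 <- s0 + sample(minLen:(ti[["end"]] - s0), 1L)
        strand[i] <- "-"
      } else if (sp == "cryptic_tss") {
        w <- config$crypticTssSites$weight
        site <- config$crypticTssSites$position[
          sample.int(nrow(config$crypticTssSites), 1L, prob = w)]
        Ttail <- drawTailLength(config, expected)
        s0 <- as.integer(site); e0 <- pa[["start"]] + min(Ttail, expected)
      } else if (sp == "readthrough") {
        ext <- sample.int(refLen - pa[["end"]], 1L)
        s0 <- ti[["start"]]; e0 <- pa[["end"]] + ext
      } else if (sp == "full_length") {
        Ttail <- drawTailLength(config, expected)
        s0 <- ti[["start"]]; e0 <- pa[["start"]] + min(Ttail, expected)
      } else if (sp == "trunc5") {
        Ttail <- drawTailLength(config, expected)
        s0 <- sample((tg[["start"]] + 1L):(u3[["start"]] - 1L), 1L)
        e0 <- pa[["start"]] + min(Ttail, expected)
      } else if (sp == "trunc3") {
        s0 <- ti[["start"]]
        e0 <- sample((cdsI[["start"]] + 1L):(u3[["end"]] - 1L), 1L)
      } else {  # trunc_both
        s0 <- sample((tg[["start"]] + 1L):(u3[["start"]] - 1L), 1L)
        lo <- max(cdsI[["start"]], s0) + 1L
        e0 <- sample(lo:(u3[["end"]] - 1L), 1L)
      }

      template <- if (sp == "contaminant") substr(contaminant, s0 + 1L, e0)
                  else substr(refseq, s0 + 1L, e0)
      tmask <- if (sp == "contaminant") NULL else tailMaskFull[(s0 + 1L):e0]
      pprob <- if (!is.null(psiRef) && sp != "contaminant")
        psiRef[(s0 + 1L):e0] else NULL
      ed <- applyErrorModel(template, em, tailMask = tmask, psiProb = pprob)

      ## soft-clipped extra tail: encoded overshoot + optional enzymatic tail
      extra <- 0L
      if (hasTail && Ttail > expected) extra <- extra + (Ttail - expected)
      if (config$polyadenylateAll)
        extra <- extra + rgeom(1L, 1 / (1 + config$extraTailMean))
      readSeq <- ed$seq; cig <- ed$cigar
      if (extra > 0L && sp != "contaminant") {
        if (strand[i] == "+") {
          readSeq <- paste0(readSeq, strrep("A", extra))
          cig <- paste0(cig, extra, "S")
        } else {
          ## molecule 3' tail sits at the alignment's left end for antisense
          readSeq <- paste0(strrep("T", extra), readSeq)
          cig <- paste0(extra, "S", cig)
        }
      } else if (extra > 0L) {
        readSeq <- paste0(readSeq, strrep("A", extra))
      }

      seqs[i] <- readSeq
      cigars[i] <- cig
      refStart[i] <- s0; refEnd[i] <- e0
      tailLen[i] <- if (hasTail) Ttail else 0L
      nmm[i] <- ed$counts[["mismatch"]]
      nins[i] <- ed$counts[["insertion"]]
      ndel[i] <- ed$counts[["deletion"]]
      quals[i] <- strrep(qualChar, nchar(readSeq))
    }

    reads <- data.frame(read_id = ids,
                        seq = seqs,          # reference orientation (SAM SEQ)
                        qual = quals,
                        cigar = cigars,
                        ref_start = refStart,
                        strand = strand,
                        mapped = src == "construct",
                        stringsAsFactors = FALSE)
    truth <- data.frame(read_id = ids,
                        true_class = species,
                        true_ref_start = refStart,
                        true_ref_end = refEnd,
                        true_strand = strand,
                        true_tail_length = tailLen,
                        source = src,
                        n_mismatch = nmm, n_insertion = nins, n_deletion = ndel,
                        stringsAsFactors = FALSE)
    structure(list(reads = reads, truth = truth, layout = layout,
                   config = config),
              class = "mrnaqc_simulation")
  })
}

#' @export
print.mrnaqc_simulation <- function(x, ...) {
  cat(sprintf("mrnaqc simulation: %d reads on %s (seed %d)\n",
              nrow(x$reads), referenceId(x$layout), x$config$seed))
  print(table(x$truth$true_class))
  invisible(x)
}

#' Write simulated reads as FASTQ
#'
#' Reads are written in sequencing (read) orientation: antisense reads are
#' reverse-complemented relative to the reference-forward sequence held in
#' the truth alignments.
#'
#' @param sim an `mrnaqc_simulation`.
#' @param path output FASTQ path.
#' @return invisibly, `path`.
#' @export
writeSimulatedFastq <- function(sim, path) {
  rd <- sim$reads
  seqs <- rd$seq
  rev <- rd$strand == "-"
  if (any(rev)) {
    seqs[rev] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[rev])))
  }
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(rd$qual))
  names(x) <- rd$read_id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Write truth alignments as SAM
#'
#' Emits one record per read: construct-origin reads are mapped at their
#' true position with a CIGAR equal to the edit walk (antisense reads carry
#' the reverse-strand flag, with SEQ in reference-forward orientation as SAM
#' requires); contaminant reads are emitted as unmapped records with their
#' sequence retained, so contamination triage can be exercised downstream.
#'
#' @param sim an `mrnaqc_simulation`.
#' @param path output SAM path.
#' @return invisibly, `path`.
#' @export
writeTruthAlignments <- function(sim, path) {
  rd <- sim$reads
  lay <- sim$layout
  refLen <- length(lay@sequence)
  ## consistency: CIGAR query width must equal |SEQ| for mapped reads
  m <- rd$mapped
  if (any(m)) {
    qw <- GenomicAlignments::cigarWidthAlongQuerySpace(rd$cigar[m])
    if (!all(qw == nchar(rd$seq[m])))
      stopf("edit walk inconsistent with read length for %s",
            rd$read_id[m][which(qw != nchar(rd$seq[m]))[1L]])
  }
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", referenceId(lay), refLen),
           "@PG\tID:mrnaqc\tPN:mrnaqc")
  flag <- ifelse(rd$mapped, ifelse(rd$strand == "-", 16L, 0L), 4L)
  rname <- ifelse(rd$mapped, referenceId(lay), "*")
  pos <- ifelse(rd$mapped, rd$ref_start + 1L, 0L)
  mapq <- ifelse(rd$mapped, 60L, 0L)
  cig <- ifelse(rd$mapped, rd$cigar, "*")
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                 rd$read_id, flag, rname, pos, mapq, cig, rd$seq, rd$qual)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write the truth table as TSV
#'
#' @param sim an `mrnaqc_simulation`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeTruthTable <- function(sim, path) {
  write.table(sim$truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
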