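## Contaminant triage by k-mer containment and antisense-fraction logic.

#' Build a canonical k-mer index of a reference
#'
#' Stores the strand-canonical (lexicographic min of k-mer and reverse
#' complement) k-mer set of a reference sequence. Containment screening
#' against such indexes replaces a second alignment pass for the triage of
#' unmapped reads.
#'
#' @param reference character or DNAString, length >= k.
#' @param k odd k-mer size in `[11, 31]` (default 21).
#' @param label source label reported in triage output.
#' @return `mrnaqc_kmer_index` list with `k`, `kmers` (unique canonical
#'   set), `label`.
#' @export
buildKmerIndex <- function(reference, k = 21L, label = "contaminant") {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 11L || k > 31L)
    stopf("k must be odd and in [11, 31]")
  s <- toupper(as.character(reference))
  L <- nchar(s)
  if (L < k) stopf("reference (%d nt) shorter than k = %d", L, k)
  kmers <- unique(canonicalKmers(s, k))
  structure(list(k = k, kmers = kmers, label = label),
            class = "mrnaqc_kmer_index")
}

## All canonical k-mers of one sequence (character vector, possibly with
## duplicates).
canonicalKmers <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character())
  km <- substring(s, 1:(L - k + 1L), k:L)
  ## k-mers of the reverse complement, reversed, are the per-k-mer reverse
  ## complements — one revcomp of the whole sequence instead of one per k-mer
  rcs <- revcompChar(s)
  rc <- rev(substring(rcs, 1:(L - k + 1L), k:L))
  ifelse(km <= rc, km, rc)
}

#' @export
print.mrnaqc_kmer_index <- function(x, ...) {
  cat(sprintf("k-mer index '%s': %d canonical %d-mers\n",
              x$label, length(x$kmers), x$k))
  invisible(x)
}

#' Triage unmapped reads against reference k-mer indexes
#'
#' For each read, the containment against an index is the fraction of the
#' read's canonical k-mers present in the index. The read is labelled with
#' the argmax-containment source when the maximum reaches
#' `minContainment`, else `unclassified`; reads shorter than k are
#' unclassified but counted. Canonicalisation makes the triage invariant
#' under read reverse-complementation.
#'
#' @param reads data.frame with `read_id` and `seq` columns (typically the
#'   unmapped subset from [loadAlignments()]), or a character vector of
#'   sequences.
#' @param indexes list of [buildKmerIndex()] objects (at least one); all
#'   must share the same k.
#' @param minContainment containment needed to assign a label (default 0.5,
#'   tolerant of 5-8% read error at k = 21).
#' @return list with `labels` (per-read data.frame: `read_id`, `label`,
#'   `containment`) and `summary` (counts and fractions per label plus
#'   `unclassified`; counts sum to the number of reads presented).
#' @export
classifyUnmapped <- function(reads, indexes, minContainment = 0.5) {
  if (inherits(indexes, "mrnaqc_kmer_index")) indexes <- list(indexes)
  if (!length(indexes)) stopf("at least one k-mer index is required")
  ks <- vapply(indexes, `[[`, 1L, "k")
  if (length(unique(ks)) != 1L) stopf("all indexes must share the same k")
  k <- ks[1L]
  labels <- vapply(indexes, `[[`, "", "label")
  if (anyDuplicated(labels)) stopf("index labels must be unique")
  if (is.character(reads))
    reads <- data.frame(read_id = sprintf("read%d", seq_along(reads)),
                        seq = reads, stringsAsFactors = FALSE)
  n <- nrow(reads)
  lab <- rep("unclassified", n)
  best <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    km <- canonicalKmers(toupper(reads$seq[i]), k)
    if (!length(km)) next
    cont <- vapply(indexes, function(ix) mean(km %in% ix$kmers), 0)
    j <- which.max(cont)
    best[i] <- cont[j]
    if (cont[j] >= minContainment) lab[i] <- labels[j]
  }
  out <- data.frame(read_id = reads$read_id, label = lab, containment = best,
                    stringsAsFactors = FALSE)
  lv <- c(labels, "unclassified")
  counts <- table(factor(lab, levels = lv))
  list(labels = out,
       summary = list(counts = setNames(as.integer(counts), lv),
                      fractions = setNames(as.numeric(counts) / max(n, 1L), lv),
                      n_reads = n))
}

#' Antisense read fraction
#'
#' Long single-end mode trusts the alignment strand: a read is antisense
#' iff its reverse-strand flag is set (orientation is assumed resolved
#' upstream by the strand-switch chemistry). Paired stranded mode uses the
#' mate/strand truth table of a stranded protocol: a fragment originates
#' from the forward (sense) strand iff its second-in-pair mate maps forward
#' or its first-in-pair mate maps reverse; the converse combinations are
#' antisense. Antisense RNA can anneal to the product to form
#' immunostimulatory dsRNA, so this fraction is an indirect dsRNA proxy.
#'
#' @param reads data.frame of mapped primary records.
#' @param mode `"long_single_end"` or `"paired_stranded"`.
#' @return proportion of antisense (reverse-origin) reads.
#' @export
antisenseFraction <- function(reads, mode = c("long_single_end",
                                              "paired_stranded")) {
  mode <- match.arg(mode)
  if (!nrow(reads)) return(NA_real_)
  if (mode == "long_single_end") return(mean(reads$is_reverse))
  if (any(!reads$is_paired))
    stopf("paired_stranded mode requires paired reads (%d unpaired)",
          sum(!reads$is_paired))
  senseOrigin <- (reads$is_second_in_pair & !reads$is_reverse) |
    (reads$is_first_in_pair & reads$is_reverse)
  antisenseOrigin <- (reads$is_second_in_pair & reads$is_reverse) |
    (reads$is_first_in_pair & !reads$is_reverse)
  sum(antisenseOrigin) / (sum(senseOrigin) + sum(antisenseOrigin))
}
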