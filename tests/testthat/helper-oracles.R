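# Independent brute-force oracles and tiny fixtures. These deliberately
# share no code with the package internals they check.

# Naive per-read CIGAR replay pileup: walk each record character by
# character and tally. Returns list(counts = L x 5 matrix (A,C,G,T,del),
# ins = integer L).
oracleReplayPileup <- function(reads, refLen) {
  counts <- matrix(0L, nrow = refLen, ncol = 5L,
                   dimnames = list(NULL, c("A", "C", "G", "T", "del")))
  ins <- integer(refLen)
  for (i in seq_len(nrow(reads))) {
    if (isTRUE(reads$is_unmapped[i])) next
    cig <- reads$cigar[i]
    lens <- as.integer(regmatches(cig, gregexpr("\\d+", cig))[[1]])
    ops <- regmatches(cig, gregexpr("[A-Z=]", cig))[[1]]
    rpos <- reads$ref_start[i] + 1L   # 1-based
    qpos <- 1L
    sq <- reads$seq[i]
    for (j in seq_along(ops)) {
      op <- ops[j]; l <- lens[j]
      if (op %in% c("M", "=", "X")) {
        for (t in 0:(l - 1L)) {
          b <- substr(sq, qpos + t, qpos + t)
          if (b %in% c("A", "C", "G", "T"))
            counts[rpos + t, b] <- counts[rpos + t, b] + 1L
        }
        rpos <- rpos + l; qpos <- qpos + l
      } else if (op == "D") {
        for (t in 0:(l - 1L)) counts[rpos + t, "del"] <- counts[rpos + t, "del"] + 1L
        rpos <- rpos + l
      } else if (op == "I") {
        a <- max(rpos - 1L, 1L)
        ins[a] <- ins[a] + 1L
        qpos <- qpos + l
      } else if (op == "S") {
        qpos <- qpos + l
      } else stop("oracle: unexpected op ", op)
    }
  }
  list(counts = counts, ins = ins)
}

# Replay an edit walk (CIGAR) against the input sequence and check it is
# arithmetically consistent with the output sequence; returns TRUE/FALSE.
oracleWalkConsistent <- function(input, cigar, output) {
  lens <- as.integer(regmatches(cigar, gregexpr("\\d+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  nIn <- sum(lens[ops %in% c("M", "=", "X", "D")])
  nOut <- sum(lens[ops %in% c("M", "=", "X", "I", "S")])
  nIn == nchar(input) && nOut == nchar(output)
}

# A small construct for fast tests: 30 nt tail, 60 nt CDS, 100 nt backbone.
tinyLayout <- function() {
  set.seed(2024)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                   prob = c(0.22, 0.28, 0.28, 0.22)),
                            collapse = "")
  seqs <- paste0(rand(10),              # promoter  [0,10)
                 rand(10),              # utr5      [10,20)
                 "GCCAC",               # kozak     [20,25)
                 rand(60),              # cds       [25,85)
                 rand(20),              # utr3      [85,105)
                 "GCATC",               # linker    [105,110)
                 strrep("A", 30),       # polya     [110,140)
                 "GGTCTC",              # restriction_site [140,146)
                 rand(100))             # backbone  [146,246)
  regions <- data.frame(
    name = c("promoter", "utr5", "kozak", "cds", "utr3", "linker", "polya",
             "restriction_site", "backbone"),
    start = c(0L, 10L, 20L, 25L, 85L, 105L, 110L, 140L, 146L),
    end = c(10L, 20L, 25L, 85L, 105L, 110L, 140L, 146L, 246L))
  ConstructLayout("tiny1", seqs, regions)
}

# One-row alignment-record data.frame in loadAlignments() layout.
readRecord <- function(read_id, ref_start, cigar, seq,
                       qual = strrep("-", nchar(seq)),
                       reverse = FALSE, unmapped = FALSE, secondary = FALSE,
                       supplementary = FALSE, paired = FALSE, first = FALSE,
                       second = FALSE, mean_qual = 12) {
  flag <- 4L * unmapped + 16L * reverse + 256L * secondary +
    2048L * supplementary + 1L * paired + 64L * first + 128L * second
  data.frame(read_id = read_id, flag = flag, is_unmapped = unmapped,
             is_secondary = secondary, is_supplementary = supplementary,
             is_reverse = reverse, is_paired = paired,
             is_first_in_pair = first, is_second_in_pair = second,
             ref_start = if (unmapped) NA_integer_ else as.integer(ref_start),
             cigar = cigar, seq = seq, qual = qual, mean_qual = mean_qual,
             stringsAsFactors = FALSE)
}

# Build a PileupProfile directly from a counts specification.
pileupFromCounts <- function(reference, counts, ins = NULL) {
  if (is.null(ins)) ins <- integer(nchar(as.character(reference)))
  new("PileupProfile", referenceId = "manual",
      reference = Biostrings::DNAString(as.character(reference)),
      counts = counts, insertions = as.integer(ins))
}

emptyCounts <- function(L) {
  matrix(0L, nrow = L, ncol = 5L,
         dimnames = list(NULL, c("A", "C", "G", "T", "del")))
}

binomSE <- function(p, n) sqrt(p * (1 - p) / n)
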