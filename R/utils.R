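# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
#' state afterwards.
#' @noRd
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## 0-based half-open interval [start, end)
asInterval <- function(start, end) {
  stopifnot(length(start) == 1L, length(end) == 1L, start < end)
  c(start = as.integer(start), end = as.integer(end))
}

intervalLength <- function(x) unname(x[["end"]] - x[["start"]])

#' Random DNA string of a given length from the current RNG stream.
#' @noRd
randomDNA <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse-complement of a plain character DNA string.
#' @noRd
revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Byte-level base codes used by the pileup (A=1, C=2, G=3, T=4, other=NA).
BASE_CODE <- local({
  m <- rep(NA_integer_, 256L)
  m[utf8ToInt("A")] <- 1L; m[utf8ToInt("C")] <- 2L
  m[utf8ToInt("G")] <- 3L; m[utf8ToInt("T")] <- 4L
  m[utf8ToInt("a")] <- 1L; m[utf8ToInt("c")] <- 2L
  m[utf8ToInt("g")] <- 3L; m[utf8ToInt("t")] <- 4L
  m
})

BASES <- c("A", "C", "G", "T")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
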