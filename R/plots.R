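## Secondary plotting helpers (ggplot2, Suggests). All acceptance surfaces
## are the TSV/JSON numbers; these are for eyeballing runs.

needGgplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("plotting requires the ggplot2 package")
}

#' Plot a per-nucleotide error profile
#'
#' Stacked per-position mismatch/deletion/insertion rates along the
#' reference. Insertion rates are capped at 1 for display only.
#'
#' @param profile an `mrnaqc_error_profile`.
#' @return a ggplot object.
#' @export
plotErrorProfile <- function(profile) {
  needGgplot()
  p <- profile[profile$defined, , drop = FALSE]
  long <- rbind(
    data.frame(position = p$position, rate = p$mismatch, type = "mismatch"),
    data.frame(position = p$position, rate = p$deletion, type = "deletion"),
    data.frame(position = p$position, rate = pmin(p$insertion, 1),
               type = "insertion"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$rate,
                                     fill = .data$type)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "reference position (0-based)", y = "error rate") +
    ggplot2::theme_minimal()
}

#' Plot a read length distribution
#'
#' @param lengths integer vector from [readLengths()].
#' @param binWidth histogram bin width (nt).
#' @param expectedLength optional vertical marker.
#' @return a ggplot object.
#' @export
plotReadLengths <- function(lengths, binWidth = 25L, expectedLength = NULL) {
  needGgplot()
  g <- ggplot2::ggplot(data.frame(length = as.integer(lengths)),
                       ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(binwidth = binWidth) +
    ggplot2::labs(x = "read length (nt)", y = "reads") +
    ggplot2::theme_minimal()
  if (!is.null(expectedLength))
    g <- g + ggplot2::geom_vline(xintercept = expectedLength, linetype = 2)
  g
}

#' Plot corrected poly(A) tail length density
#'
#' @param estimates data.frame from [correctTailLengths()].
#' @param expectedLength optional vertical marker (nt).
#' @return a ggplot object.
#' @export
plotTailLengths <- function(estimates, expectedLength = NULL) {
  needGgplot()
  x <- estimates[estimates$spans_tail_end & !is.na(estimates$corrected_length), ]
  g <- ggplot2::ggplot(x, ggplot2::aes(x = .data$corrected_length)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "corrected poly(A) tail length (nt)", y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(expectedLength))
    g <- g + ggplot2::geom_vline(xintercept = expectedLength, linetype = 2)
  g
}
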