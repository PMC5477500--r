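#' Select the top-scoring peaks
#'
#' Keeps the \code{n} peaks with the highest caller scores (all peaks when
#' fewer than \code{n}); the low-stringency selection step of the screen.
#' Score ties at the boundary are resolved deterministically by
#' (chromosome, start).
#'
#' @param peaks A peak set with a \code{score} metadata column.
#' @param n Number of peaks to keep (default 3000).
#' @return The selected subset, in (chromosome, start) order.
#' @export
select_top_peaks <- function(peaks, n = 3000) {
  if (length(n) != 1L || is.na(n) || n <= 0) {
    stop("n must be a positive integer", call. = FALSE)
  }
  if (any(!is.finite(peaks$score))) {
    stop("peak scores must be finite", call. = FALSE)
  }
  if (length(peaks) <= n) return(sort_genomic(peaks))
  o <- order(-peaks$score,
             as.character(GenomicRanges::seqnames(peaks)),
             GenomicRanges::start(peaks))
  sort_genomic(peaks[o[seq_len(n)]])
}

#' Filter peaks by ChIP/input enrichment
#'
#' The high-stringency rule of the screen: retain peaks whose
#' log2(ChIP/input ratio) is at least \code{log2_threshold} (default 4,
#' i.e. a 16-fold ratio; the boundary value is retained under the
#' inclusive rule, set \code{strict = TRUE} for a strictly-greater cut).
#'
#' @param peaks A peak set with an \code{enrichment} metadata column.
#' @param log2_threshold Threshold on log2 enrichment (default 4).
#' @param strict Use strict inequality instead of \code{>=}.
#' @return The retained subset.
#' @export
filter_high_stringency <- function(peaks, log2_threshold = 4, strict = FALSE) {
  if (is.null(peaks$enrichment) || any(peaks$enrichment <= 0)) {
    stop("peaks need positive ChIP/input enrichment values", call. = FALSE)
  }
  lg <- log2(peaks$enrichment)
  peaks[if (strict) lg > log2_threshold else lg >= log2_threshold]
}

#' Windows around peak reference positions
#'
#' Builds the interval covering \code{flank} bp on each side of every
#' peak's reference position (summit, or midpoint when absent): in 0-based
#' terms \code{[ref - flank, ref + flank)}, i.e. width \code{2 * flank},
#' clipped at the chromosome start.
#'
#' @param peaks A peak set.
#' @param flank Positive flank size in bp.
#' @param rule Reference-position rule, see [peak_reference_points()].
#' @return A \code{GRanges} of windows, parallel to \code{peaks}.
#' @export
summit_window <- function(peaks, flank, rule = c("summit", "midpoint")) {
  stopifnot(length(flank) == 1L, flank > 0)
  rule <- match.arg(rule)
  ref <- peak_reference_points(peaks, rule)
  s <- pmax(1L, as.integer(ref - flank))
  e <- as.integer(ref + flank - 1L)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                IRanges::IRanges(s, e))
  S4Vectors::mcols(out)$name <- peaks$name
  out
}
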