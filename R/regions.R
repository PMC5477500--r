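#' Parse a UCSC-style region string
#'
#' Parses strings such as \code{"chr3:151,022,847-151,023,000"} into a
#' [GenomicRanges::GRanges] of length one. Printed genome-browser coordinates
#' are 1-based with closed ends, which is also the internal convention used
#' throughout this package, so the printed width is
#' \code{end - start + 1}. Thousands separators (commas) are accepted and
#' stripped.
#'
#' @param text Character vector of region strings of the form
#'   \code{"chrom:start-end"}.
#' @return A \code{GRanges} with one range per input string and unstranded
#'   (\code{*}) strand.
#' @examples
#' ire <- parse_region_string("chr3:151,022,847-151,023,000")
#' GenomicRanges::width(ire)  # 154
#' @export
parse_region_string <- function(text) {
  stopifnot(is.character(text), length(text) >= 1L)
  m <- regmatches(text, regexec("^([^:[:space:]]+):([0-9,]+)-([0-9,]+)$", text))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed region string: '", text[bad][1L], "'", call. = FALSE)
  }
  chrom <- vapply(m, `[[`, character(1), 2L)
  start <- as.numeric(gsub(",", "", vapply(m, `[[`, character(1), 3L)))
  end <- as.numeric(gsub(",", "", vapply(m, `[[`, character(1), 4L)))
  if (any(start < 1)) {
    stop("region start must be >= 1 in '", text[start < 1][1L], "'",
         call. = FALSE)
  }
  if (any(start > end)) {
    stop("region start exceeds end in '", text[start > end][1L], "'",
         call. = FALSE)
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

#' Format genomic ranges as region strings
#'
#' Inverse of [parse_region_string()]: formats each range as
#' \code{"chrom:start-end"} in printed 1-based closed coordinates.
#'
#' @param x A \code{GRanges}.
#' @param big_mark Thousands separator to insert (default \code{","}, as in
#'   genome browsers; use \code{""} for none).
#' @return Character vector of region strings.
#' @export
format_region_string <- function(x, big_mark = ",") {
  stopifnot(methods::is(x, "GRanges"))
  fmt <- function(v) formatC(v, format = "d", big.mark = big_mark)
  paste0(
    as.character(GenomicRanges::seqnames(x)), ":",
    fmt(GenomicRanges::start(x)), "-", fmt(GenomicRanges::end(x))
  )
}

#' Separation between two printed regions
#'
#' Distance between two non-overlapping regions measured on the printed
#' coordinates as \code{start(downstream) - end(upstream)}, i.e. the offset
#' from the edge of one element to the first base of the other, counted
#' inclusively. This is the convention in which a reporter element "located
#' at 1,703 bp upstream" of another is separated by 1,703 bp; it is one more
#' than the number of bases strictly between the two intervals.
#'
#' @param a,b Single-range \code{GRanges} on the same chromosome.
#' @return Integer separation in bp (positive when the ranges are disjoint).
#' @export
region_separation <- function(a, b) {
  stopifnot(methods::is(a, "GRanges"), methods::is(b, "GRanges"),
            length(a) == 1L, length(b) == 1L)
  if (as.character(GenomicRanges::seqnames(a)) !=
      as.character(GenomicRanges::seqnames(b))) {
    stop("regions lie on different chromosomes", call. = FALSE)
  }
  lo <- if (GenomicRanges::start(a) <= GenomicRanges::start(b)) a else b
  hi <- if (GenomicRanges::start(a) <= GenomicRanges::start(b)) b else a
  as.integer(GenomicRanges::start(hi) - GenomicRanges::end(lo))
}
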