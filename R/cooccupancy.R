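#' Fraction of query peaks overlapping a subject peak set
#'
#' A query peak counts as overlapping when it shares at least
#' \code{min_overlap} bp with any subject peak (whole peak intervals, not
#' summits; strand ignored).
#'
#' @param query,subject \code{GRanges} peak sets on the same chromosome
#'   namespace.
#' @param mark_name Optional label for the subject set.
#' @param min_overlap Minimum shared bp to count an overlap (default 1).
#' @return One-row \code{data.frame}: \code{mark}, \code{n_query},
#'   \code{n_overlapping}, \code{fraction}.
#' @export
overlap_fraction <- function(query, subject, mark_name = NA_character_,
                             min_overlap = 1L) {
  if (length(query) == 0L) {
    stop("empty query peak set", call. = FALSE)
  }
  hit <- IRanges::overlapsAny(query, subject, minoverlap = min_overlap,
                              ignore.strand = TRUE)
  data.frame(mark = mark_name, n_query = length(query),
             n_overlapping = sum(hit), fraction = mean(hit),
             stringsAsFactors = FALSE)
}

#' Rank histone marks by co-occupancy with a peak set
#'
#' Computes [overlap_fraction()] of the query against each named mark peak
#' set and orders the result by fraction (descending), breaking ties by mark
#' name.
#'
#' @param query A \code{GRanges} peak set.
#' @param marks Named list of \code{GRanges} mark peak sets.
#' @param min_overlap Minimum shared bp to count an overlap.
#' @return \code{data.frame} with one row per mark, ordered by descending
#'   overlap fraction.
#' @export
rank_marks <- function(query, marks, min_overlap = 1L) {
  stopifnot(is.list(marks), length(marks) >= 1L, !is.null(names(marks)))
  rows <- lapply(names(marks), function(m) {
    overlap_fraction(query, marks[[m]], mark_name = m,
                     min_overlap = min_overlap)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$fraction, out$mark), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition peaks by overlap with nucleosome-turnover regions
#'
#' @param peaks A \code{GRanges} peak set.
#' @param turnover_regions \code{GRanges} of high-turnover regions.
#' @param min_overlap Minimum shared bp to count an overlap.
#' @return List with elements \code{high} (peaks overlapping at least one
#'   region) and \code{low} (the rest); together a partition of the input.
#' @export
stratify_by_turnover <- function(peaks, turnover_regions, min_overlap = 1L) {
  hit <- IRanges::overlapsAny(peaks, turnover_regions,
                              minoverlap = min_overlap, ignore.strand = TRUE)
  list(high = peaks[hit], low = peaks[!hit])
}

#' Histone-mark occupancy by turnover stratum
#'
#' For each mark coverage track, computes per-peak mean RPKM over the
#' \code{[-flank, +flank)} window around the reference position of every
#' peak in the high and low strata, and compares the two value sets with a
#' Wilcoxon rank-sum test (descriptive; the alternative is
#' \code{high != low} by default, or \code{high > low} with
#' \code{alternative = "greater"}).
#'
#' @param high,low Peak sets for the two strata (both nonempty).
#' @param mark_tracks Named list of [coverage_track()] objects.
#' @param flank Half-window in bp (default 1000).
#' @param alternative Passed to [stats::wilcox.test()] (high vs low).
#' @return List with \code{summary} (data frame per mark: n, medians,
#'   rank-sum statistic W and p-value) and \code{values} (per mark, the two
#'   per-stratum RPKM vectors).
#' @export
mark_occupancy_by_stratum <- function(high, low, mark_tracks, flank = 1000,
                                      alternative = "two.sided") {
  if (length(high) == 0L || length(low) == 0L) {
    stop("both turnover strata must be nonempty", call. = FALSE)
  }
  stopifnot(is.list(mark_tracks), !is.null(names(mark_tracks)))
  win_h <- summit_window(high, flank)
  win_l <- summit_window(low, flank)
  window_rpkm <- function(track, win) {
    counts <- coverage_query(track, win)
    counts / (GenomicRanges::width(win) / 1000) / (track$total_reads / 1e6)
  }
  values <- lapply(mark_tracks, function(tr) {
    list(high = window_rpkm(tr, win_h), low = window_rpkm(tr, win_l))
  })
  summary <- do.call(rbind, lapply(names(values), function(m) {
    v <- values[[m]]
    wt <- suppressWarnings(
      stats::wilcox.test(v$high, v$low, alternative = alternative,
                         exact = FALSE)
    )
    data.frame(mark = m, n_high = length(v$high), n_low = length(v$low),
               median_high = stats::median(v$high),
               median_low = stats::median(v$low),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(summary = summary, values = values)
}
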