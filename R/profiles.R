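#' Binned RPKM over a window
#'
#' Splits a window into contiguous fixed-width bins and computes, per bin,
#' reads per kilobase per million mapped reads:
#' \deqn{RPKM = count / (bin\_size/1000) / (total\_reads/10^6)}
#' where \code{count} is the summed per-base coverage in the bin
#' (fragment-depth semantics).
#'
#' @param track A [coverage_track()] with positive \code{total_reads}.
#' @param window A single-range \code{GRanges} whose width is a multiple of
#'   \code{bin_size}.
#' @param bin_size Bin width in bp.
#' @return Numeric vector of per-bin RPKM values.
#' @export
binned_rpkm <- function(track, window, bin_size) {
  stopifnot(inherits(track, "coverage_track"), methods::is(window, "GRanges"),
            length(window) == 1L)
  if (track$total_reads <= 0) {
    stop("coverage track has zero total_reads", call. = FALSE)
  }
  w <- GenomicRanges::width(window)
  if (w %% bin_size != 0L) {
    stop("bin_size must divide the window length", call. = FALSE)
  }
  vec <- window_coverage(track,
                         as.character(GenomicRanges::seqnames(window)),
                         GenomicRanges::start(window),
                         GenomicRanges::end(window))
  counts <- colSums(matrix(vec, nrow = bin_size))
  counts / (bin_size / 1000) / (track$total_reads / 1e6)
}

# Per-base coverage over [s, e] (1-based closed); positions outside the
# stored extent are 0. s may not be < 1 here (mask such bins upstream).
window_coverage <- function(track, chrom, s, e) {
  n <- e - s + 1L
  if (!chrom %in% names(track$cov)) return(numeric(n))
  r <- track$cov[[chrom]]
  lo <- max(1L, s)
  hi <- min(length(r), e)
  out <- numeric(n)
  if (lo <= hi) {
    out[(lo - s + 1L):(hi - s + 1L)] <-
      as.numeric(S4Vectors::window(r, lo, hi))
  }
  out
}

#' Summit-centered occupancy profile matrix
#'
#' Builds the peaks-by-bins matrix of binned RPKM around each peak's
#' reference position (summit, or midpoint when absent): bins of
#' \code{bin_size} bp spanning \code{[-flank, +flank)}. Rows are in input
#' peak order. Bins that would extend past the chromosome start are masked
#' (\code{NA}) rather than dropped.
#'
#' @param peaks A peak set.
#' @param track A [coverage_track()].
#' @param flank Half-window in bp (default 2000); must be a multiple of
#'   \code{bin_size}.
#' @param bin_size Bin width in bp (default 20).
#' @param rule Reference-position rule, see [peak_reference_points()].
#' @return An object of class \code{profile_matrix}: list with
#'   \code{values} (numeric matrix, peaks x bins, \code{NA} = masked),
#'   \code{bin_offsets} (0-based offsets of bin starts from the reference
#'   position), \code{row_meta} (data frame with \code{name},
#'   \code{target_gene}, \code{expression}, \code{group}), \code{flank},
#'   \code{bin_size}.
#' @export
profile_matrix <- function(peaks, track, flank = 2000, bin_size = 20,
                           rule = c("summit", "midpoint")) {
  stopifnot(flank > 0, bin_size > 0)
  if ((2 * flank) %% bin_size != 0L) {
    stop("bin_size must divide 2*flank", call. = FALSE)
  }
  if (track$total_reads <= 0) {
    stop("coverage track has zero total_reads", call. = FALSE)
  }
  rule <- match.arg(rule)
  ref <- peak_reference_points(peaks, rule)
  ch <- as.character(GenomicRanges::seqnames(peaks))
  nbin <- as.integer(2 * flank / bin_size)
  vals <- matrix(NA_real_, nrow = length(peaks), ncol = nbin)
  for (i in seq_along(peaks)) {
    s <- ref[i] - flank          # 1-based start of the full window
    e <- ref[i] + flank - 1L
    vec <- window_coverage(track, ch[i], s, e)
    counts <- colSums(matrix(vec, nrow = bin_size))
    rpkm <- counts / (bin_size / 1000) / (track$total_reads / 1e6)
    # mask bins not fully on the chromosome (genomic position >= 1)
    bin_starts <- s + (seq_len(nbin) - 1L) * bin_size
    rpkm[bin_starts < 1L] <- NA_real_
    vals[i, ] <- rpkm
  }
  meta <- data.frame(
    name = if (is.null(peaks$name)) paste0("peak_", seq_along(peaks))
           else peaks$name,
    target_gene = if (is.null(peaks$target_gene)) NA_character_
                  else peaks$target_gene,
    expression = NA_real_,
    group = NA_character_,
    stringsAsFactors = FALSE
  )
  structure(
    list(values = vals,
         bin_offsets = as.integer(seq(-flank, flank - bin_size, by = bin_size)),
         row_meta = meta, flank = as.integer(flank),
         bin_size = as.integer(bin_size)),
    class = "profile_matrix"
  )
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix: ", nrow(x$values), " peak(s) x ", ncol(x$values),
      " bins of ", x$bin_size, " bp spanning +/-", x$flank, " bp\n", sep = "")
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$values)

#' Attach expression values and sort rows by target-gene expression
#'
#' Rows whose target gene has an expression value are kept and sorted in
#' descending expression order (ties by gene id, then original order); rows
#' without a target or without expression are dropped, with a message
#' giving the count.
#'
#' @param pm A [profile_matrix()].
#' @param expression Named numeric vector of expression values per gene id.
#' @return The reordered \code{profile_matrix} with \code{expression}
#'   filled in \code{row_meta}.
#' @export
sort_rows_by_expression <- function(pm, expression) {
  stopifnot(inherits(pm, "profile_matrix"), !is.null(names(expression)))
  expr <- expression[match(pm$row_meta$target_gene, names(expression))]
  keep <- !is.na(expr)
  if (any(!keep)) {
    message(sum(!keep), " row(s) without a target-gene expression value dropped")
  }
  idx <- which(keep)
  o <- idx[order(-expr[idx], pm$row_meta$target_gene[idx], idx)]
  pm$values <- pm$values[o, , drop = FALSE]
  pm$row_meta <- pm$row_meta[o, , drop = FALSE]
  pm$row_meta$expression <- as.numeric(expr[o])
  rownames(pm$row_meta) <- NULL
  pm
}

#' Tertile expression groups
#'
#' Splits values into equal-count high / intermediate / low groups by rank
#' (stable for ties: earlier elements get the lower rank). Group sizes
#' differ by at most one; when the count is not divisible by 3 the extra
#' members go to the low, then intermediate, group.
#'
#' @param values Numeric vector (length >= 3).
#' @return Factor with levels \code{c("high", "intermediate", "low")},
#'   parallel to \code{values}.
#' @export
expression_groups <- function(values) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 values to form tertiles", call. = FALSE)
  r <- rank(values, ties.method = "first")
  k <- n %/% 3L
  n_low <- k + as.integer(n %% 3L >= 1L)
  n_int <- k + as.integer(n %% 3L == 2L)
  lab <- rep("high", n)
  lab[r <= n_low] <- "low"
  lab[r > n_low & r <= n_low + n_int] <- "intermediate"
  factor(lab, levels = c("high", "intermediate", "low"))
}

#' Per-group average occupancy profile
#'
#' Arithmetic mean of each bin within each group; masked (\code{NA}) bins
#' are excluded from the mean.
#'
#' @param pm A [profile_matrix()].
#' @param labels Group labels parallel to the rows (factor or character).
#' @return Numeric matrix, groups x bins, rownames = group labels.
#' @export
group_average_profile <- function(pm, labels) {
  stopifnot(inherits(pm, "profile_matrix"),
            length(labels) == nrow(pm$values))
  labels <- as.factor(labels)
  empty <- setdiff(levels(labels), as.character(unique(labels)))
  if (length(empty) > 0L) {
    stop("empty expression group: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  out <- t(vapply(levels(labels), function(g) {
    colMeans(pm$values[labels == g, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(pm$values))))
  rownames(out) <- levels(labels)
  out
}

#' Locally weighted scatterplot smoothing of a profile
#'
#' Classical lowess at unit-spaced positions: at each index the value is a
#' tricube-weighted linear regression over the \code{ceiling(f * n)} nearest
#' points, with no robustness iterations (deterministic). A constant input
#' is reproduced exactly, and with \code{f = 1} an exactly linear input is
#' reproduced exactly.
#'
#' @param y Numeric vector (length >= 2).
#' @param f Smoother span as a fraction of the data (default 0.3).
#' @return Smoothed numeric vector of the same length.
#' @export
lowess_smooth <- function(y, f = 0.3) {
  n <- length(y)
  if (n < 2L) stop("need at least 2 points to smooth", call. = FALSE)
  stopifnot(f > 0, f <= 1)
  x <- seq_len(n)
  r <- min(n, max(2L, as.integer(ceiling(f * n))))
  out <- numeric(n)
  for (i in x) {
    d <- abs(x - i)
    h <- sort(d, partial = r)[r]  # >= 1: positions are distinct integers
    w <- numeric(n)
    inb <- d < h
    w[inb] <- (1 - (d[inb] / h)^3)^3
    sw <- sum(w)
    xw <- sum(w * x) / sw
    yw <- sum(w * y) / sw
    sxx <- sum(w * (x - xw)^2)
    b <- if (sxx > 0) sum(w * (x - xw) * (y - yw)) / sxx else 0
    out[i] <- yw + b * (i - xw)
  }
  out
}
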