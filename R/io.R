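#' Read gene models from a GTF file
#'
#' Parses a GTF (1-based closed coordinates, converted to the internal
#' \code{GRanges} convention on import, which is identical) and returns one
#' model per \code{gene_id}, with exons merged across transcripts. Gene spans
#' are taken from \code{gene} features when present, otherwise from the range
#' of each gene's exons. Models are ordered by (chromosome, start, gene_id).
#'
#' @param path Path to a GTF file.
#' @return A [gene_models] object.
#' @export
read_gene_models <- function(path) {
  validate_gtf_lines(path)
  ln <- readLines(path)
  if (!any(!grepl("^#", ln) & nzchar(trimws(ln)))) {
    return(empty_gene_models())
  }
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0L) return(empty_gene_models())
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stop("GTF contains no exon features", call. = FALSE)
  exons <- S4Vectors::split(GenomicRanges::granges(ex), ex$gene_id)
  gn <- gr[gr$type == "gene"]
  if (length(gn) > 0L && all(names(exons) %in% gn$gene_id)) {
    spans <- GenomicRanges::granges(gn)
    S4Vectors::mcols(spans)$gene_id <- gn$gene_id
    spans <- spans[match(names(exons), spans$gene_id)]
  } else {
    spans <- unlist(range(exons))
    S4Vectors::mcols(spans)$gene_id <- names(spans)
    names(spans) <- NULL
  }
  gene_models(spans, exons)
}

empty_gene_models <- function() {
  g <- GenomicRanges::GRanges()
  S4Vectors::mcols(g)$gene_id <- character(0)
  gene_models(g, GenomicRanges::GRangesList())
}

# Structural pre-scan so errors can name the offending GTF line.
validate_gtf_lines <- function(path) {
  ln <- readLines(path)
  keep <- !grepl("^#", ln) & nzchar(trimws(ln))
  for (i in which(keep)) {
    f <- strsplit(ln[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) {
      stop("GTF line ", i, ": expected 9 tab-separated fields", call. = FALSE)
    }
    s <- suppressWarnings(as.numeric(f[4L]))
    e <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(s) || is.na(e) || s > e) {
      stop("GTF line ", i, ": invalid interval [", f[4L], ", ", f[5L], "]",
           call. = FALSE)
    }
    if (!f[7L] %in% c("+", "-")) {
      stop("GTF line ", i, ": unknown strand '", f[7L], "'", call. = FALSE)
    }
    if (f[3L] %in% c("gene", "exon") && !grepl("gene_id", f[9L], fixed = TRUE)) {
      stop("GTF line ", i, ": missing gene_id attribute", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Construct a peak set
#'
#' Peaks are held as a \code{GRanges} (1-based closed) with metadata columns
#' \code{name}, \code{score} (caller peak score), \code{enrichment}
#' (ChIP/input ratio) and \code{summit} (absolute 1-based position of maximal
#' enrichment, or \code{NA} when the caller reported none).
#'
#' @param chrom,start,end Vectors of chromosome, 1-based start and closed
#'   end.
#' @param name Peak names (default \code{peak_1 ...}).
#' @param score Numeric peak scores.
#' @param enrichment Positive ChIP/input ratios.
#' @param summit Absolute 1-based summit positions, \code{NA} for absent.
#' @return A \code{GRanges} peak set, sorted by (chromosome, start).
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = 0,
                     enrichment = 1, summit = NA_integer_) {
  n <- length(start)
  if (is.null(name)) name <- paste0("peak_", seq_len(n))
  gr <- GenomicRanges::GRanges(rep_len(chrom, n),
                               IRanges::IRanges(start, end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = name,
    score = as.numeric(rep_len(score, n)),
    enrichment = as.numeric(rep_len(enrichment, n)),
    summit = as.integer(rep_len(summit, n))
  )
  ok <- is.na(gr$summit) |
    (gr$summit >= GenomicRanges::start(gr) & gr$summit <= GenomicRanges::end(gr))
  if (!all(ok)) {
    stop("summit outside peak interval for: ",
         paste(gr$name[!ok], collapse = ", "), call. = FALSE)
  }
  if (any(gr$enrichment <= 0)) {
    stop("enrichment (ChIP/input ratio) must be > 0", call. = FALSE)
  }
  sort_genomic(gr)
}

sort_genomic <- function(gr) {
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr), GenomicRanges::end(gr))
  gr[o]
}

#' Read peaks from a narrowPeak or BED file
#'
#' narrowPeak (BED6+4) files carry the summit as a 0-based offset from the
#' peak start in column 10; an offset of \code{-1} means no summit was
#' reported. Plain BED files yield peaks without summits. BED's 0-based
#' half-open coordinates are converted to 1-based closed on import; summit
#' positions become absolute 1-based coordinates. The narrowPeak
#' \code{signalValue} column is kept as the ChIP/input \code{enrichment}.
#'
#' @param path Path to a narrowPeak or BED file.
#' @return A \code{GRanges} peak set as from [peak_set()], sorted by
#'   (chromosome, start).
#' @export
read_peaks <- function(path) {
  first <- readLines(path, n = 1L)
  ncol <- if (length(first) == 0L) 0L else
    length(strsplit(first, "\t", fixed = TRUE)[[1L]])
  if (ncol == 0L) {
    return(peak_set(character(0), integer(0), integer(0)))
  }
  if (ncol == 10L) {
    gr <- rtracklayer::import(path, format = "BED",
      extraCols = c(signalValue = "numeric", pValue = "numeric",
                    qValue = "numeric", peak = "integer"))
    if (any(gr$peak >= GenomicRanges::width(gr))) {
      stop("narrowPeak summit offset >= peak length at: ",
           paste(gr$name[gr$peak >= GenomicRanges::width(gr)], collapse = ", "),
           call. = FALSE)
    }
    summit <- ifelse(gr$peak < 0L, NA_integer_,
                     GenomicRanges::start(gr) + gr$peak)
    enr <- gr$signalValue
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    summit <- NA_integer_
    enr <- 1
  }
  if (length(gr) == 0L) {
    return(peak_set(character(0), integer(0), integer(0)))
  }
  score <- if (is.null(gr$score)) 0 else as.numeric(gr$score)
  if (anyNA(score)) stop("non-numeric peak score in ", path, call. = FALSE)
  nm <- if (is.null(gr$name)) paste0("peak_", seq_along(gr)) else gr$name
  peak_set(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr), GenomicRanges::end(gr),
           name = nm, score = score, enrichment = enr, summit = summit)
}

#' Write peaks as narrowPeak
#'
#' Converts back to BED's 0-based half-open convention; summits become
#' 0-based offsets from the peak start (\code{-1} when absent).
#'
#' @param x A peak set from [peak_set()] or [read_peaks()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_peaks <- function(x, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1L,
    end = GenomicRanges::end(x),
    name = x$name,
    score = x$score,
    strand = ".",
    signalValue = x$enrichment,
    pValue = -1,
    qValue = -1,
    peak = ifelse(is.na(x$summit), -1L,
                  x$summit - GenomicRanges::start(x))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write intervals as BED
#'
#' @param x A \code{GRanges}; a \code{name} metadata column is used when
#'   present.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_bed <- function(x, path) {
  nm <- if (is.null(x$name)) paste0("region_", seq_along(x)) else x$name
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1L,
    end = GenomicRanges::end(x),
    name = nm
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a coverage track
#'
#' A coverage track holds per-base read coverage as one run-length-encoded
#' vector per chromosome plus the library size used for RPKM normalization.
#'
#' @param cov A named \code{RleList} (or named list of \code{Rle}) of
#'   non-negative per-base coverage, one element per chromosome.
#' @param total_reads Positive library total of mapped reads. Defaults to the
#'   summed per-base coverage across the track (fragment-depth semantics).
#' @return An object of class \code{coverage_track}.
#' @export
coverage_track <- function(cov, total_reads = NULL) {
  cov <- methods::as(cov, "RleList")
  if (length(cov) && any(vapply(cov, function(r) any(r < 0), logical(1)))) {
    stop("coverage values must be non-negative", call. = FALSE)
  }
  if (is.null(total_reads)) {
    total_reads <- sum(vapply(cov, function(r) sum(as.numeric(r)), numeric(1)))
  }
  if (length(cov) > 0L && total_reads <= 0) {
    stop("total_reads must be positive", call. = FALSE)
  }
  structure(list(cov = cov, total_reads = as.numeric(total_reads)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track: ", length(x$cov), " chromosome(s), total_reads = ",
      format(x$total_reads), "\n", sep = "")
  invisible(x)
}

#' Read a bedGraph coverage file
#'
#' Intervals must be non-overlapping within each chromosome and values
#' non-negative. Uncovered positions have coverage 0.
#'
#' @param path Path to a bedGraph file.
#' @param total_reads Library size; default as in [coverage_track()].
#' @return A [coverage_track()].
#' @export
read_coverage <- function(path, total_reads = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(gr$score < 0)) {
    stop("negative coverage value in ", path, call. = FALSE)
  }
  if (!IRanges::isDisjoint(gr)) {
    stop("overlapping bedGraph intervals in ", path, call. = FALSE)
  }
  cov <- GenomicRanges::coverage(gr, weight = gr$score)
  coverage_track(cov, total_reads)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal coverage are written as single records; zero-coverage runs
#' are omitted. Output uses BED-style 0-based half-open coordinates.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_coverage <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$cov)) {
    r <- track$cov[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r)  # already 0-based starts
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    if (any(keep)) {
      writeLines(paste(ch, starts[keep], ends[keep],
                       format(vals[keep], trim = TRUE, scientific = FALSE),
                       sep = "\t"),
                 con)
    }
  }
  invisible(path)
}

#' Total coverage over genomic intervals
#'
#' Sums per-base coverage over each query interval. Chromosomes absent from
#' the track, and positions beyond its recorded extent, count as zero.
#'
#' @param track A [coverage_track()].
#' @param regions A \code{GRanges} of query intervals.
#' @return Numeric vector of per-interval coverage sums.
#' @export
coverage_query <- function(track, regions) {
  stopifnot(inherits(track, "coverage_track"), methods::is(regions, "GRanges"))
  vapply(seq_along(regions), function(i) {
    ch <- as.character(GenomicRanges::seqnames(regions))[i]
    if (!ch %in% names(track$cov)) return(0)
    r <- track$cov[[ch]]
    s <- max(1L, GenomicRanges::start(regions)[i])
    e <- min(length(r), GenomicRanges::end(regions)[i])
    if (s > e) return(0)
    sum(as.numeric(S4Vectors::window(r, s, e)))
  }, numeric(1))
}

#' Read and write tab-separated tables
#'
#' Thin wrappers with the package's conventions: header row, tab separator,
#' no quoting, no row names, strings kept as strings. \code{read_tsv_table}
#' and \code{write_tsv_table} round-trip a data frame exactly (up to numeric
#' formatting).
#'
#' @param path File path.
#' @return \code{read_tsv_table}: a \code{data.frame}.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' @param x A \code{data.frame}.
#' @rdname read_tsv_table
#' @return \code{write_tsv_table}: invisibly, \code{path}.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
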