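#' Partition the genome into promoter/exon/intron/intergenic features
#'
#' Builds a genome-wide feature labeling from gene models. Every base
#' receives exactly one label under the priority
#' promoter > exon > intron > intergenic, applied across all overlapping
#' genes: the promoter window of one gene masks the exon or intron of a
#' neighbour, an exon of any gene masks introns, and positions inside no
#' gene span or promoter are intergenic.
#'
#' The promoter window is \code{upstream} bp 5' of the TSS to
#' \code{downstream} bp 3' of it, oriented by strand, clipped at position 1.
#'
#' @param genes A [gene_models] object.
#' @param promoter_window Length-2 non-negative integer vector
#'   \code{c(upstream, downstream)} in bp around the TSS. Default
#'   \code{c(2000, 500)}, a common promoter convention.
#' @return An object of class \code{feature_map}.
#' @export
build_feature_map <- function(genes, promoter_window = c(2000, 500)) {
  stopifnot(inherits(genes, "gene_models"),
            length(promoter_window) == 2L, all(promoter_window >= 0))
  g <- genes$genes
  if (length(g) > 0L) {
    prom <- GenomicRanges::promoters(
      g, upstream = promoter_window[1L], downstream = promoter_window[2L]
    )
    prom <- GenomicRanges::restrict(prom, start = 1L)
    prom <- GenomicRanges::reduce(prom, ignore.strand = TRUE)
    ex <- GenomicRanges::reduce(unlist(genes$exons), ignore.strand = TRUE)
    spans <- GenomicRanges::reduce(g, ignore.strand = TRUE)
  } else {
    prom <- ex <- spans <- GenomicRanges::GRanges()
  }
  structure(
    list(promoters = prom, exons = ex, spans = spans,
         promoter_window = as.integer(promoter_window),
         chroms = unique(as.character(GenomicRanges::seqnames(g)))),
    class = "feature_map"
  )
}

#' @export
print.feature_map <- function(x, ...) {
  cat("feature_map: promoter window (-", x$promoter_window[1L], ", +",
      x$promoter_window[2L], ") bp; ", length(x$chroms),
      " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Feature label at genomic positions
#'
#' @param fmap A [build_feature_map()] result.
#' @param chrom Chromosome names (recycled against \code{pos}).
#' @param pos 1-based positions.
#' @return Character vector of labels in
#'   \{promoter, exon, intron, intergenic\}.
#' @export
feature_at <- function(fmap, chrom, pos) {
  stopifnot(inherits(fmap, "feature_map"))
  pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  lab <- rep("intergenic", length(pts))
  inside <- function(set) IRanges::overlapsAny(pts, set, ignore.strand = TRUE)
  lab[inside(fmap$spans)] <- "intron"
  lab[inside(fmap$exons)] <- "exon"
  lab[inside(fmap$promoters)] <- "promoter"
  lab
}

#' Reference position of each peak
#'
#' The summit where available, otherwise the peak midpoint
#' (floor of the mean of the 0-based boundaries, reported 1-based) --
#' mirroring peak callers' "summit or peak center" reference positions.
#'
#' @param peaks A peak set from [peak_set()] or [read_peaks()].
#' @param rule \code{"summit"} (midpoint only as fallback) or
#'   \code{"midpoint"} (always the midpoint).
#' @return Integer vector of 1-based reference positions.
#' @export
peak_reference_points <- function(peaks, rule = c("summit", "midpoint")) {
  rule <- match.arg(rule)
  s <- GenomicRanges::start(peaks)
  e <- GenomicRanges::end(peaks)
  mid <- as.integer(floor((s - 1 + e) / 2) + 1)
  if (rule == "midpoint" || is.null(peaks$summit)) return(mid)
  ifelse(is.na(peaks$summit), mid, peaks$summit)
}

#' Annotate peaks by genomic feature and target gene
#'
#' Each peak's feature category is the label of its single reference
#' position (summit, or midpoint when absent). The target gene is the
#' nearest gene within \code{max_dist} bp of the peak interval
#' (see [assign_target_gene()]).
#'
#' @param peaks A peak set.
#' @param fmap A [build_feature_map()] result.
#' @param genes A [gene_models] object (used for target assignment; omit
#'   with \code{NULL} to skip).
#' @param max_dist Maximum peak-to-gene distance in bp (default 10000, the
#'   10-kb cis-regulatory target rule).
#' @param rule Reference-position rule, see [peak_reference_points()].
#' @return The input \code{GRanges} with added metadata columns
#'   \code{category}, \code{target_gene} (\code{NA} if none within range)
#'   and \code{target_distance}.
#' @export
annotate_peaks <- function(peaks, fmap, genes = NULL, max_dist = 10000,
                           rule = c("summit", "midpoint")) {
  stopifnot(inherits(fmap, "feature_map"))
  rule <- match.arg(rule)
  ref <- peak_reference_points(peaks, rule)
  ch <- as.character(GenomicRanges::seqnames(peaks))
  if (length(fmap$chroms) > 0L && !all(ch %in% fmap$chroms)) {
    stop("peak reference position on unknown chromosome: ",
         paste(unique(ch[!ch %in% fmap$chroms]), collapse = ", "),
         call. = FALSE)
  }
  S4Vectors::mcols(peaks)$category <- feature_at(fmap, ch, ref)
  if (!is.null(genes)) {
    tg <- assign_target_gene(peaks, genes, max_dist = max_dist)
    S4Vectors::mcols(peaks)$target_gene <- tg$gene_id
    S4Vectors::mcols(peaks)$target_distance <- tg$distance
  }
  peaks
}

#' Assign the nearest gene within a distance cutoff
#'
#' Distance is 0 when the peak interval overlaps the gene span, otherwise
#' the number of bases strictly between the closest boundaries. The
#' minimal-distance gene wins; ties are broken by smaller gene start, then
#' lexicographic gene id. Genes farther than \code{max_dist} give no target.
#' Strand is ignored.
#'
#' @param peaks A peak set (\code{GRanges}).
#' @param genes A [gene_models] object.
#' @param max_dist Maximum distance in bp (default 10000).
#' @return A \code{data.frame} with one row per peak: \code{gene_id}
#'   (character, \code{NA} if none) and \code{distance} (\code{NA} if none).
#' @export
assign_target_gene <- function(peaks, genes, max_dist = 10000) {
  stopifnot(inherits(genes, "gene_models"))
  n <- length(peaks)
  out <- data.frame(gene_id = rep(NA_character_, n),
                    distance = rep(NA_integer_, n))
  g <- genes$genes
  if (n == 0L || length(g) == 0L) return(out)
  # all candidate genes within max_dist (gap semantics), so that
  # equidistant ties on opposite sides can be broken deterministically
  hits <- GenomicRanges::findOverlaps(peaks, g, maxgap = max_dist,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(peaks[qh], g[sh], ignore.strand = TRUE)
  keep <- !is.na(d) & d <= max_dist
  qh <- qh[keep]
  sh <- sh[keep]
  d <- d[keep]
  if (length(qh) == 0L) return(out)
  # deterministic tie-break: distance, then gene start, then gene_id
  o <- order(qh, d, GenomicRanges::start(g)[sh], gene_ids(genes)[sh])
  first <- o[!duplicated(qh[o])]
  out$gene_id[qh[first]] <- gene_ids(genes)[sh[first]]
  out$distance[qh[first]] <- as.integer(d[first])
  out
}

#' Genomic distribution of annotated peaks
#'
#' @param annotated Peaks annotated by [annotate_peaks()] (or anything with
#'   a \code{category} metadata column / a character vector of categories).
#' @return Named numeric vector of fractions over the four feature labels
#'   (promoter, exon, intron, intergenic), summing to 1.
#' @export
genomic_distribution <- function(annotated) {
  cat <- if (is.character(annotated)) annotated else annotated$category
  if (is.null(cat) || length(cat) == 0L) {
    stop("no annotated peaks to summarize", call. = FALSE)
  }
  labels <- c("promoter", "exon", "intron", "intergenic")
  bad <- setdiff(unique(cat), labels)
  if (length(bad) > 0L) {
    stop("unknown feature category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tab <- table(factor(cat, levels = labels))
  frac <- as.numeric(tab) / length(cat)
  names(frac) <- labels
  frac
}
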