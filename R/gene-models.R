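#' Construct a set of gene models
#'
#' A \code{gene_models} object bundles, per gene, the gene span, strand,
#' transcription start site (TSS) and the merged exon set, from which introns
#' are derived as the within-span complement of the exons. Coordinates are
#' 1-based closed throughout (the \code{GRanges} convention).
#'
#' @param genes A stranded \code{GRanges} of gene spans with a
#'   \code{gene_id} metadata column (unique).
#' @param exons A \code{GRangesList}, parallel to \code{genes}, of exon
#'   intervals. Exons are merged (reduced) per gene and must lie within the
#'   gene span.
#' @return An object of class \code{gene_models}: a list with elements
#'   \code{genes} (spans, with \code{gene_id} and \code{tss} metadata
#'   columns, ordered by chromosome, start, gene_id) and \code{exons}
#'   (reduced \code{GRangesList}, parallel to \code{genes}).
#' @export
gene_models <- function(genes, exons) {
  stopifnot(methods::is(genes, "GRanges"), methods::is(exons, "GRangesList"),
            length(genes) == length(exons))
  gid <- S4Vectors::mcols(genes)$gene_id
  if (is.null(gid) || anyDuplicated(gid)) {
    stop("gene spans need a unique 'gene_id' metadata column", call. = FALSE)
  }
  st <- as.character(GenomicRanges::strand(genes))
  if (any(!st %in% c("+", "-"))) {
    stop("unknown strand for gene(s): ",
         paste(gid[!st %in% c("+", "-")], collapse = ", "), call. = FALSE)
  }
  exons <- GenomicRanges::reduce(exons)
  within <- unlist(exons) %within% rep(genes, lengths(exons))
  if (!all(within)) {
    off <- rep(gid, lengths(exons))[!within]
    stop("exon outside declared gene span for gene(s): ",
         paste(unique(off), collapse = ", "), call. = FALSE)
  }
  S4Vectors::mcols(genes)$tss <- ifelse(
    st == "+", GenomicRanges::start(genes), GenomicRanges::end(genes)
  )
  o <- order(as.character(GenomicRanges::seqnames(genes)),
             GenomicRanges::start(genes), gid)
  structure(list(genes = genes[o], exons = exons[o]), class = "gene_models")
}

`%within%` <- function(x, y) {
  as.logical(IRanges::poverlaps(x, y, type = "within"))
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models: ", length(x$genes), " genes on ",
      length(unique(as.character(GenomicRanges::seqnames(x$genes)))),
      " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @export
length.gene_models <- function(x) length(x$genes)

#' Gene identifiers of a gene_models object
#' @param x A \code{gene_models} object.
#' @return Character vector of gene ids, in object order.
#' @export
gene_ids <- function(x) {
  stopifnot(inherits(x, "gene_models"))
  S4Vectors::mcols(x$genes)$gene_id
}

#' Intron intervals of gene models
#'
#' Introns are the parts of each gene span not covered by exons.
#'
#' @param x A \code{gene_models} object.
#' @return A \code{GRangesList} parallel to the genes (possibly with empty
#'   elements for intronless genes).
#' @export
gene_introns <- function(x) {
  stopifnot(inherits(x, "gene_models"))
  out <- GenomicRanges::psetdiff(x$genes, x$exons)
  names(out) <- gene_ids(x)
  out
}
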