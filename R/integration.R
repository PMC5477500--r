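#' Select differentially expressed genes by the opposite-direction rule
#'
#' Implements the fold-change rule used to call DEGs from paired
#' overexpression/knockdown contrasts: a gene is \emph{positively} regulated
#' when its expression moves up under overexpression and down under
#' knockdown, with the fold threshold exceeded in at least one of the two
#' contrasts ("greater than \code{fold_threshold}-fold in either, opposite
#' responses in both"); \emph{negatively} regulated genes are the mirror
#' image. Set \code{both_contrasts = TRUE} for the stricter variant that
#' requires the threshold in both contrasts.
#'
#' The knockdown fold uses the \code{knockdown_control} column when present,
#' otherwise the shared \code{control}.
#'
#' @param table Data frame with a \code{gene_id} column (unique ids) and
#'   positive intensity columns \code{control}, \code{overexpression},
#'   \code{knockdown}, optionally \code{knockdown_control}.
#' @param fold_threshold Fold-change threshold (> 1; default 2).
#' @param both_contrasts Require the fold threshold in both contrasts.
#' @return An object of class \code{deg_result}: list with \code{positive}
#'   and \code{negative} (character vectors of gene ids, disjoint) and
#'   \code{fold_changes} (data frame of per-gene log2 fold changes for the
#'   overexpression and knockdown contrasts).
#' @export
select_degs <- function(table, fold_threshold = 2, both_contrasts = FALSE) {
  fc <- contrast_folds(table)
  if (fold_threshold <= 1) {
    stop("fold_threshold must be > 1", call. = FALSE)
  }
  thr_oe <- pmax(fc$oe_fold, 1 / fc$oe_fold) > fold_threshold
  thr_kd <- pmax(fc$kd_fold, 1 / fc$kd_fold) > fold_threshold
  thr <- if (both_contrasts) thr_oe & thr_kd else thr_oe | thr_kd
  pos <- fc$oe_fold > 1 & fc$kd_fold < 1 & thr
  neg <- fc$oe_fold < 1 & fc$kd_fold > 1 & thr
  structure(
    list(
      positive = fc$gene_id[pos],
      negative = fc$gene_id[neg],
      fold_changes = data.frame(
        gene_id = fc$gene_id,
        log2_oe = log2(fc$oe_fold),
        log2_kd = log2(fc$kd_fold),
        stringsAsFactors = FALSE
      ),
      fold_threshold = fold_threshold,
      both_contrasts = both_contrasts
    ),
    class = "deg_result"
  )
}

contrast_folds <- function(table) {
  need <- c("gene_id", "control", "overexpression", "knockdown")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0L) {
    stop("expression table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(table$gene_id)) {
    stop("expression table ids must be unique", call. = FALSE)
  }
  kd_ctrl <- if ("knockdown_control" %in% names(table)) {
    table$knockdown_control
  } else {
    table$control
  }
  vals <- cbind(table$control, table$overexpression, table$knockdown, kd_ctrl)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("expression intensities must be positive and finite", call. = FALSE)
  }
  list(gene_id = as.character(table$gene_id),
       oe_fold = table$overexpression / table$control,
       kd_fold = table$knockdown / kd_ctrl)
}

#' @export
print.deg_result <- function(x, ...) {
  cat("deg_result: ", length(x$positive), " positively / ",
      length(x$negative), " negatively regulated genes (",
      if (x$both_contrasts) "both contrasts" else "either contrast",
      " > ", x$fold_threshold, "-fold, opposite directions)\n", sep = "")
  invisible(x)
}

#' Rank opposite-direction probes by fold change
#'
#' The low-stringency expression funnel: among probes responding in
#' opposite directions under overexpression and knockdown, rank by the
#' larger absolute log2 fold change of the two contrasts and return the top
#' \code{n} ids (ties broken by id).
#'
#' @inheritParams select_degs
#' @param n Number of probes to return (default 3000).
#' @return Character vector of at most \code{n} gene/probe ids.
#' @export
rank_degs <- function(table, n = 3000) {
  stopifnot(n >= 0)
  fc <- contrast_folds(table)
  opp <- (fc$oe_fold > 1 & fc$kd_fold < 1) | (fc$oe_fold < 1 & fc$kd_fold > 1)
  key <- pmax(abs(log2(fc$oe_fold)), abs(log2(fc$kd_fold)))[opp]
  ids <- fc$gene_id[opp]
  ids[order(-key, ids)][seq_len(min(n, length(ids)))]
}

#' Genes whose intronic peaks are co-occupied by a histone mark
#'
#' @param intronic_peaks Annotated peaks (from [annotate_peaks()]) carrying
#'   a \code{target_gene} metadata column; typically pre-filtered to the
#'   intron category.
#' @param mark_peaks \code{GRanges} of mark peaks.
#' @param min_overlap Minimum shared bp to count an overlap (default 1).
#' @return Sorted character vector of target-gene ids having at least one
#'   peak overlapping at least one mark peak.
#' @export
genes_with_cooccupied_introns <- function(intronic_peaks, mark_peaks,
                                          min_overlap = 1L) {
  if (length(intronic_peaks) == 0L) return(character(0))
  if (is.null(intronic_peaks$target_gene)) {
    stop("peaks carry no target_gene annotation", call. = FALSE)
  }
  hit <- IRanges::overlapsAny(intronic_peaks, mark_peaks,
                              minoverlap = min_overlap, ignore.strand = TRUE)
  g <- intronic_peaks$target_gene[hit]
  sort(unique(g[!is.na(g)]))
}

#' Nominate direct targets by set intersection
#'
#' The Venn step of the screen: genes supported both by ChIP occupancy and
#' by opposite-direction differential expression.
#'
#' @param chip_genes Character vector of gene ids from the ChIP funnel.
#' @param deg_genes Character vector of gene ids from the expression funnel.
#' @return Sorted character vector, the exact intersection.
#' @export
nominate_targets <- function(chip_genes, deg_genes) {
  sort(intersect(unique(chip_genes), unique(deg_genes)))
}
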