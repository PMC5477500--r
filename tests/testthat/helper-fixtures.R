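# Shared toy fixtures, built in code at test time.

# Two genes on a 20 kb chromosome: one + strand, one - strand, 2 exons each.
# Returns both the gene_models object and a plain-list description that the
# brute-force oracles work from independently.
toy_genes <- function() {
  desc <- list(
    list(gene_id = "gA", chrom = "chrT", start = 4001, end = 7000,
         strand = "+", exons = list(c(4001, 4800), c(6201, 7000))),
    list(gene_id = "gB", chrom = "chrT", start = 11001, end = 14000,
         strand = "-", exons = list(c(11001, 11900), c(13101, 14000)))
  )
  gm <- gene_models_from_desc(desc)
  list(gm = gm, desc = desc, chrom = "chrT", chrom_len = 20000L)
}

gene_models_from_desc <- function(desc) {
  genes <- GenomicRanges::GRanges(
    vapply(desc, `[[`, character(1), "chrom"),
    IRanges::IRanges(vapply(desc, `[[`, numeric(1), "start"),
                     vapply(desc, `[[`, numeric(1), "end")),
    strand = vapply(desc, `[[`, character(1), "strand")
  )
  S4Vectors::mcols(genes)$gene_id <- vapply(desc, `[[`, character(1),
                                            "gene_id")
  exons <- GenomicRanges::GRangesList(lapply(desc, function(g) {
    GenomicRanges::GRanges(
      g$chrom,
      IRanges::IRanges(vapply(g$exons, `[`, numeric(1), 1),
                       vapply(g$exons, `[`, numeric(1), 2)),
      strand = g$strand
    )
  }))
  gene_models(genes, exons)
}

# Coverage track over one chromosome from an explicit per-base vector.
toy_track <- function(values, chrom = "chrT", total_reads = NULL) {
  rl <- methods::as(stats::setNames(list(S4Vectors::Rle(values)), chrom),
                    "RleList")
  coverage_track(rl, total_reads)
}

random_peaks <- function(n, chrom = "chrT", chrom_len = 20000L,
                         width = 200L) {
  s <- sample.int(chrom_len - width, n, replace = TRUE)
  peak_set(chrom, s, s + width - 1L,
           score = stats::runif(n), enrichment = stats::runif(n, 1, 40),
           summit = s + sample.int(width, n, replace = TRUE) - 1L)
}

small_config <- function(seed = 5, ...) {
  sim_config(seed = seed, n_genes = 60,
             n_peaks = c(intronic = 20, promoter = 15, intergenic = 15),
             deg_counts = c(positive = 5, negative = 3),
             n_patients = 40, ...)
}
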