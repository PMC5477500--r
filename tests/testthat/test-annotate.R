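test_that("feature labels match the per-base brute-force labeler", {
  toy <- toy_genes()
  fmap <- build_feature_map(toy$gm)
  withr::local_seed(101)
  pos <- sample.int(toy$chrom_len, 10000, replace = TRUE)
  expect_identical(feature_at(fmap, toy$chrom, pos),
                   oracle_feature_label(toy$desc, pos))
  # all four labels are exercised on this fixture
  expect_setequal(unique(feature_at(fmap, toy$chrom, pos)),
                  c("promoter", "exon", "intron", "intergenic"))
})

test_that("promoter windows are strand-oriented and take priority", {
  toy <- toy_genes()
  fmap <- build_feature_map(toy$gm, promoter_window = c(2000, 500))
  # 1 kb upstream of the + strand TSS (4001) is promoter
  expect_identical(feature_at(fmap, "chrT", 3001), "promoter")
  # 1 kb upstream of the - strand TSS (14000) means higher coordinate
  expect_identical(feature_at(fmap, "chrT", 15000), "promoter")
  # inside exon 2 of gA, between exons is intron
  expect_identical(feature_at(fmap, "chrT", 6500), "exon")
  expect_identical(feature_at(fmap, "chrT", 5000), "intron")
  # an exon position that also sits in another gene's promoter window
  desc <- list(
    list(gene_id = "g1", chrom = "chrT", start = 1000, end = 3000,
         strand = "+", exons = list(c(1000, 1400), c(2600, 3000))),
    list(gene_id = "g2", chrom = "chrT", start = 4000, end = 6000,
         strand = "+", exons = list(c(4000, 6000)))
  )
  fm2 <- build_feature_map(gene_models_from_desc(desc))
  expect_identical(feature_at(fm2, "chrT", 2800), "promoter")
  expect_identical(
    feature_at(fm2, "chrT", 2800),
    oracle_feature_label(desc, 2800)
  )
})

test_that("no genes means intergenic everywhere", {
  gm0 <- gene_models_from_desc(list())
  fmap <- build_feature_map(gm0)
  expect_identical(feature_at(fmap, "chrZ", c(1, 1e6, 5e7)),
                   rep("intergenic", 3))
})

test_that("mirrored genome gives mirrored promoter labels", {
  toy <- toy_genes()
  L <- toy$chrom_len
  flip <- function(v) c(L - v[2] + 1, L - v[1] + 1)
  mirrored <- lapply(toy$desc, function(g) {
    list(gene_id = g$gene_id, chrom = g$chrom,
         start = L - g$end + 1, end = L - g$start + 1,
         strand = if (g$strand == "+") "-" else "+",
         exons = lapply(rev(g$exons), flip))
  })
  fm1 <- build_feature_map(toy$gm)
  fm2 <- build_feature_map(gene_models_from_desc(mirrored))
  withr::local_seed(11)
  pos <- sample.int(L - 1L, 2000)
  expect_identical(feature_at(fm1, toy$chrom, pos),
                   feature_at(fm2, toy$chrom, L - pos + 1))
})

test_that("peak category is decided at the summit position", {
  toy <- toy_genes()
  fmap <- build_feature_map(toy$gm)
  # peak spans exon/intron boundary of gA but summit is intronic
  pk <- peak_set("chrT", 4700, 5200, summit = 5000)
  ann <- annotate_peaks(pk, fmap, toy$gm)
  expect_identical(ann$category, "intron")
  # same peak, summit in the exon
  pk2 <- peak_set("chrT", 4700, 5200, summit = 4750)
  expect_identical(annotate_peaks(pk2, fmap, toy$gm)$category, "exon")
  # no summit: midpoint rule
  pk3 <- peak_set("chrT", 8000, 9000)
  expect_identical(peak_reference_points(pk3), 8500L)
  expect_identical(annotate_peaks(pk3, fmap, toy$gm)$category, "intergenic")
  expect_error(
    annotate_peaks(peak_set("chrQ", 1, 100, summit = 50), fmap, toy$gm),
    "unknown chromosome"
  )
})

test_that("annotation category multiset matches the oracle on random peaks", {
  toy <- toy_genes()
  fmap <- build_feature_map(toy$gm)
  withr::local_seed(202)
  pk <- random_peaks(50, chrom = toy$chrom, chrom_len = toy$chrom_len - 300L)
  ann <- annotate_peaks(pk, fmap, toy$gm)
  expect_identical(ann$category,
                   oracle_feature_label(toy$desc, peak_reference_points(pk)))
})

test_that("nearest-gene assignment honors the 10 kb rule and tie-breaks", {
  toy <- toy_genes()
  # inside a gene: distance 0
  inside <- peak_set("chrT", 5000, 5400, summit = 5200)
  tg <- assign_target_gene(inside, toy$gm)
  expect_identical(tg$gene_id, "gA")
  expect_identical(tg$distance, 0L)
  # beyond 10 kb from every gene span: none (gB ends at 14000)
  d <- 12000L
  far_desc <- list(list(gene_id = "g", chrom = "chr9", start = 1,
                        end = 1000, strand = "+",
                        exons = list(c(1, 1000))))
  far_gm <- gene_models_from_desc(far_desc)
  far <- peak_set("chr9", 1000 + d + 1, 1000 + d + 200)
  tg2 <- assign_target_gene(far, far_gm)
  expect_true(is.na(tg2$gene_id))
  # exactly equidistant between gA (end 7000) and gB (start 11001):
  # 1900 strictly-between bases on each side -> smaller gene start wins
  eq <- peak_set("chrT", 8901, 9100)
  expect_equal(8901 - 7000 - 1, 11001 - 9100 - 1)
  tg3 <- assign_target_gene(eq, toy$gm)
  expect_identical(tg3$gene_id, "gA")
  expect_identical(tg3$distance, 1900L)
})

test_that("nearest-gene assignment equals the exhaustive scan oracle", {
  toy <- toy_genes()
  withr::local_seed(303)
  pk <- random_peaks(80, chrom = toy$chrom, chrom_len = toy$chrom_len - 300L)
  got <- assign_target_gene(pk, toy$gm)
  for (i in seq_along(pk)) {
    want <- oracle_nearest_gene(GenomicRanges::start(pk)[i],
                                GenomicRanges::end(pk)[i], toy$desc)
    expect_identical(got$gene_id[i], want$gene_id)
    expect_identical(got$distance[i], want$distance)
  }
})

test_that("target assignment is independent of gene insertion order", {
  toy <- toy_genes()
  rev_gm <- gene_models_from_desc(rev(toy$desc))
  withr::local_seed(404)
  pk <- random_peaks(40, chrom = toy$chrom, chrom_len = toy$chrom_len - 300L)
  expect_identical(assign_target_gene(pk, toy$gm),
                   assign_target_gene(pk, rev_gm))
})

test_that("genomic distribution is a normalized partition of categories", {
  cats <- c(rep("intergenic", 5), rep("intron", 4), "promoter")
  frac <- genomic_distribution(cats)
  expect_equal(unname(frac[c("intergenic", "intron", "promoter", "exon")]),
               c(0.5, 0.4, 0.1, 0))
  expect_equal(sum(frac), 1, tolerance = 1e-12)
  expect_equal(unname(genomic_distribution(rep("exon", 7))["exon"]), 1)
  expect_error(genomic_distribution(character(0)), "no annotated peaks")
  expect_error(genomic_distribution("enhancer"), "unknown feature category")
  withr::local_seed(505)
  toy <- toy_genes()
  fmap <- build_feature_map(toy$gm)
  pk <- random_peaks(200, chrom = toy$chrom, chrom_len = toy$chrom_len - 300L)
  ann <- annotate_peaks(pk, fmap, toy$gm)
  lab <- oracle_feature_label(toy$desc, peak_reference_points(pk))
  frac2 <- genomic_distribution(ann)
  expect_equal(unname(frac2["intron"]), sum(lab == "intron") / 200)
  expect_equal(sum(frac2), 1, tolerance = 1e-12)
})
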