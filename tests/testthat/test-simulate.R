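test_that("the synthetic genome is a valid non-overlapping gene grid", {
  cfg <- sim_config(seed = 61, n_genes = 50,
                    n_peaks = c(intronic = 10, promoter = 5, intergenic = 5),
                    deg_counts = c(positive = 3, negative = 2))
  gm <- simulate_genome(cfg)
  expect_length(gm, 50)
  g <- gm$genes
  expect_true(IRanges::isDisjoint(GenomicRanges::granges(g)))
  expect_identical(unique(as.character(GenomicRanges::strand(g))),
                   c("+", "-"))
  expect_true(all(lengths(gm$exons) == cfg$exons_per_gene))
  intr <- gene_introns(gm)
  expect_true(all(lengths(intr) == cfg$exons_per_gene - 1L))
  # empty genome: valid empty GTF
  cfg0 <- sim_config(seed = 62, n_genes = 0,
                     n_peaks = c(intronic = 0, promoter = 0, intergenic = 0),
                     deg_counts = c(positive = 0, negative = 0))
  gm0 <- simulate_genome(cfg0)
  expect_length(gm0, 0)
  p <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(gm0, p)
  expect_length(read_gene_models(p), 0)
  # genome too small is rejected
  expect_error(sim_config(seed = 63, n_genes = 100, chrom_length = 1000),
               "genome too small")
})

test_that("emitted files pass the package's own readers and validators", {
  cfg <- small_config(seed = 64)
  d <- withr::local_tempdir()
  st <- simulate_study(cfg, outdir = d)
  gm <- read_gene_models(file.path(d, "genes.gtf"))
  expect_length(gm, cfg$n_genes)
  pk <- read_peaks(file.path(d, "chip.narrowPeak"))
  expect_length(pk, sum(cfg$n_peaks))
  expect_equal(GenomicRanges::start(pk), GenomicRanges::start(st$peaks))
  expect_identical(pk$summit, st$peaks$summit)
  tr <- read_coverage(file.path(d, "chip.bedGraph"))
  expect_equal(tr$total_reads, st$track$total_reads)
  w <- summit_window(pk[1], 500)
  expect_equal(coverage_query(tr, w), coverage_query(st$track, w))
  expr <- read_tsv_table(file.path(d, "expr.tsv"))
  expect_identical(expr$gene_id, st$expression$gene_id)
  co <- read_tsv_table(file.path(d, "cohort.tsv"))
  expect_equal(nrow(co), cfg$n_patients)
  expect_true(all(co$time > 0))
  expect_true(all(co$event %in% c(0, 1)))
  expect_identical(co$relapse, ifelse(co$event == 1, "yes", "no"))
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(truth$target_gene, st$truth$target_gene)
})

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- small_config(seed = 65)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(cfg, outdir = d1)
  simulate_study(cfg, outdir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # a different seed changes the stochastic outputs
  d3 <- withr::local_tempdir()
  simulate_study(small_config(seed = 66), outdir = d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "expr.tsv"))),
                         unname(tools::md5sum(file.path(d3, "expr.tsv")))))
})

test_that("intronic amplitudes track expression only when coupled", {
  base_cfg <- function(slope, seed) {
    sim_config(seed = seed, n_genes = 400,
               n_peaks = c(intronic = 300, promoter = 0, intergenic = 0),
               deg_counts = c(positive = 0, negative = 0),
               occupancy_expression_slope = slope)
  }
  run <- function(cfg) {
    gm <- simulate_genome(cfg)
    sim <- simulate_expression(cfg, gene_id = gene_ids(gm))
    expr <- stats::setNames(sim$table$control, sim$table$gene_id)
    chip <- simulate_chip(cfg, gm, expr, truth = sim$truth)
    int <- chip$peak_truth$category == "intronic"
    stats::cor.test(chip$peak_truth$amplitude[int],
                    expr[chip$peak_truth$gene[int]],
                    method = "spearman", exact = FALSE)
  }
  coupled <- run(base_cfg(0.5, 67))
  expect_gt(coupled$estimate, 0)
  expect_lt(coupled$p.value, 0.01)
  null <- run(base_cfg(0, 68))
  expect_lt(abs(null$estimate), stats::qnorm(0.975) / sqrt(299))
})

test_that("background-level enrichment is removed by the stringency filter", {
  cfg <- sim_config(seed = 69, n_genes = 60,
                    n_peaks = c(intronic = 15, promoter = 10,
                                intergenic = 10),
                    deg_counts = c(positive = 0, negative = 0),
                    occupancy_expression_slope = 0,
                    amp_base = 2, amp_noise = 0, amp_sd_null = 0)
  gm <- simulate_genome(cfg)
  sim <- simulate_expression(cfg, gene_id = gene_ids(gm))
  chip <- simulate_chip(cfg, gm,
                        stats::setNames(sim$table$control,
                                        sim$table$gene_id),
                        truth = sim$truth)
  expect_true(all(chip$peaks$enrichment < 16))
  expect_length(filter_high_stringency(chip$peaks), 0)
})

test_that("planting no DEGs yields empty DEG sets", {
  cfg <- sim_config(seed = 70, n_genes = 100,
                    deg_counts = c(positive = 0, negative = 0))
  sim <- simulate_expression(cfg)
  dg <- select_degs(sim$table)
  expect_length(dg$positive, 0)
  expect_length(dg$negative, 0)
  expect_true(is.na(sim$truth$target_gene))
})

test_that("a minimal cohort is valid and hazard truth is exposed", {
  cfg <- sim_config(seed = 71, n_patients = 4)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  expect_equal(nrow(co), 4)
  expect_true(all(co$time > 0))
  expect_true(all(co$event %in% c(0L, 1L)))
  expect_true(all(names(cfg$hazard_log_hr) %in% names(co)))
  expect_length(sim$truth$rate, 4)
  expect_true(all(sim$truth$rate > 0))
  expect_error(sim_config(seed = 72, n_patients = 3), "n_patients")
})

test_that("a weak planted fold effect warns that recovery is not assured", {
  cfg <- sim_config(seed = 73, n_genes = 50,
                    deg_counts = c(positive = 5, negative = 0),
                    fold_effect = 1.5)
  expect_warning(simulate_expression(cfg), "not guaranteed")
})
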