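test_that("binned RPKM follows the count / kb / million formula", {
  # 20 bp bin holding total count 2 in a 1e6-read library -> RPKM 100
  vals <- numeric(200)
  vals[41:42] <- 1
  tr <- toy_track(vals, total_reads = 1e6)
  win <- GenomicRanges::GRanges("chrT", IRanges::IRanges(21, 60))
  expect_equal(binned_rpkm(tr, win, 20), c(0, 100))
  # zero coverage -> zero vector
  tr0 <- toy_track(numeric(500), total_reads = 1000)
  win0 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 100))
  expect_equal(binned_rpkm(tr0, win0, 10), numeric(10))
  expect_error(binned_rpkm(tr, win, 30), "divide")
  expect_error(
    binned_rpkm(coverage_track(methods::as(list(), "RleList")), win, 20),
    "total_reads"
  )
})

test_that("binned RPKM equals per-bp summation and conserves counts", {
  withr::local_seed(21)
  vals <- sample(0:7, 3000, replace = TRUE)
  tr <- toy_track(vals, total_reads = 5e5)
  win <- GenomicRanges::GRanges("chrT", IRanges::IRanges(501, 1500))
  got <- binned_rpkm(tr, win, 20)
  # direct per-bp oracle from the raw vector
  seg <- vals[501:1500]
  want <- vapply(seq_len(50), function(j) {
    sum(seg[((j - 1) * 20 + 1):(j * 20)]) / (20 / 1000) / (5e5 / 1e6)
  }, numeric(1))
  expect_equal(got, want)
  # conservation: sum(RPKM * bin_kb * total_millions) == window count, exact
  expect_equal(sum(got) * (20 / 1000) * (5e5 / 1e6), as.numeric(sum(seg)))
  # scale equivariance: doubling coverage and library leaves RPKM unchanged
  tr2 <- toy_track(vals * 2, total_reads = 1e6)
  expect_equal(binned_rpkm(tr2, win, 20), got)
})

test_that("profile matrices keep input order and mask off-genome bins", {
  withr::local_seed(22)
  vals <- sample(0:5, 6000, replace = TRUE)
  tr <- toy_track(vals, total_reads = 1e6)
  pk <- peak_set("chrT", c(101, 2901, 2901), c(301, 3101, 3101),
                 name = c("edge", "a", "b"),
                 summit = c(201, 3001, 3001))
  pm <- profile_matrix(pk, tr, flank = 1000, bin_size = 20)
  expect_equal(dim(pm), c(3L, 100L))
  expect_identical(pm$row_meta$name, c("edge", "a", "b"))
  # identical peaks give identical rows
  expect_equal(pm$values[2, ], pm$values[3, ])
  # row 1 window is [-799, 1200]: bins before position 1 are masked
  expect_true(all(is.na(pm$values[1, 1:40])))
  expect_false(anyNA(pm$values[1, 41:100]))
  # single peak matrix
  pm1 <- profile_matrix(pk[1], tr, flank = 500, bin_size = 10)
  expect_equal(dim(pm1), c(1L, 100L))
})

test_that("profile rows match brute-force window counts", {
  withr::local_seed(23)
  vals <- sample(0:9, 20000, replace = TRUE)
  tr <- toy_track(vals, total_reads = 2e6)
  pk <- random_peaks(50, chrom_len = 15000L)
  pk <- pk[GenomicRanges::start(pk) > 2200]
  pm <- profile_matrix(pk, tr, flank = 2000, bin_size = 20)
  ref <- peak_reference_points(pk)
  for (i in seq_along(pk)) {
    seg <- vals[(ref[i] - 2000):(ref[i] + 1999)]
    expect_equal(sum(pm$values[i, ]) * (20 / 1000) * 2, sum(seg),
                 tolerance = 1e-9)
  }
})

test_that("rows sort by descending target-gene expression", {
  withr::local_seed(24)
  vals <- sample(0:5, 30000, replace = TRUE)
  tr <- toy_track(vals, total_reads = 1e6)
  pk <- random_peaks(20, chrom_len = 25000L)
  pk <- pk[GenomicRanges::start(pk) > 2200]
  n <- length(pk)
  S4Vectors::mcols(pk)$target_gene <- sprintf("G%02d", seq_len(n))
  expr <- stats::setNames(stats::runif(n), sprintf("G%02d", seq_len(n)))
  pm <- profile_matrix(pk, tr, flank = 1000, bin_size = 50)
  got <- sort_rows_by_expression(pm, expr)
  expect_equal(got$row_meta$expression,
               sort(unname(expr), decreasing = TRUE))
  o <- order(-expr)
  expect_equal(got$values, pm$values[o, , drop = FALSE])
  # already sorted input is unchanged; reversing reverses
  again <- sort_rows_by_expression(got, expr)
  expect_identical(again$row_meta$target_gene, got$row_meta$target_gene)
  # rows without expression are dropped with a message
  expr2 <- expr[-3]
  expect_message(d <- sort_rows_by_expression(pm, expr2), "dropped")
  expect_equal(nrow(d$values), n - 1L)
})

test_that("expression tertiles are equal-count and rank-consistent", {
  g <- expression_groups(1:9)
  expect_identical(as.character(g[7:9]), rep("high", 3))
  expect_identical(as.character(g[4:6]), rep("intermediate", 3))
  expect_identical(as.character(g[1:3]), rep("low", 3))
  # stable split for all-equal values
  ge <- expression_groups(rep(1, 8))
  expect_true(max(table(ge)) - min(table(ge)) <= 1)
  expect_error(expression_groups(c(1, 2)), "at least 3")
  withr::local_seed(25)
  x <- stats::rnorm(100)
  gx <- expression_groups(x)
  expect_equal(sort(as.integer(table(gx)), decreasing = TRUE), c(34, 33, 33))
  # every high value outranks every low value
  expect_true(min(x[gx == "high"]) >= max(x[gx == "low"]))
  expect_true(min(x[gx == "high"]) >= max(x[gx == "intermediate"]))
})

test_that("group averages equal the explicit loop and flag empty groups", {
  withr::local_seed(26)
  vals <- sample(0:5, 9000, replace = TRUE)
  tr <- toy_track(vals, total_reads = 1e6)
  pk <- random_peaks(9, chrom_len = 6000L)
  pk <- pk[GenomicRanges::start(pk) > 1300]
  pm <- profile_matrix(pk, tr, flank = 600, bin_size = 30)
  lab <- factor(rep_len(c("high", "low"), length(pk)))
  avg <- group_average_profile(pm, lab)
  for (g in levels(lab)) {
    want <- vapply(seq_len(ncol(pm$values)), function(j) {
      mean(pm$values[lab == g, j], na.rm = TRUE)
    }, numeric(1))
    expect_equal(unname(avg[g, ]), want)
  }
  # single-row group returns that row
  one <- group_average_profile(pm, factor(c("a", rep("b", length(pk) - 1L))))
  expect_equal(unname(one["a", ]), unname(pm$values[1, ]))
  # simple two-row average
  m <- pm; m$values <- rbind(numeric(4), rep(2, 4))
  m$row_meta <- m$row_meta[1:2, ]
  expect_equal(unname(group_average_profile(m, factor(c("g", "g")))["g", ]),
               rep(1, 4))
  lab_empty <- factor(rep("a", length(pk)), levels = c("a", "ghost"))
  expect_error(group_average_profile(pm, lab_empty), "ghost")
})

test_that("lowess smoothing reproduces constants and exact lines", {
  expect_equal(lowess_smooth(rep(3.5, 40)), rep(3.5, 40), tolerance = 1e-9)
  y <- 2 + 0.5 * (1:60)
  expect_equal(lowess_smooth(y, f = 1), y, tolerance = 1e-9)
  expect_error(lowess_smooth(numeric(1)), "at least 2")
})

test_that("lowess matches a direct local-regression oracle", {
  withr::local_seed(27)
  n <- 120
  y <- sin(seq(0, 3 * pi, length.out = n)) + stats::rnorm(n, 0, 0.25)
  got <- lowess_smooth(y, f = 0.3)
  expect_equal(got, oracle_lowess(y, 0.3), tolerance = 1e-8)
  # classical reference implementation agrees where the span rules coincide
  n2 <- 200
  y2 <- cos(seq(0, 2 * pi, length.out = n2)) + stats::rnorm(n2, 0, 0.2)
  ref <- stats::lowess(seq_len(n2), y2, f = 0.3, iter = 0, delta = 0)$y
  expect_equal(lowess_smooth(y2, f = 0.3), ref, tolerance = 1e-5)
})
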