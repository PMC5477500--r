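#' Configuration for the synthetic study generator
#'
#' Bundles every tunable of the synthetic data generator with the defaults
#' that define the package's reference study conditions: a one-chromosome
#' genome of regularly spaced multi-exon genes, summit-centered Gaussian
#' ChIP enrichment whose intronic amplitude is coupled to target-gene
#' expression (and uncoupled at promoters and intergenic sites), an
#' overexpression/knockdown expression table with planted opposite-direction
#' DEGs and a unique planted intersection target, histone-mark peak sets
#' with tunable co-occupancy probabilities, nucleosome-turnover regions with
#' stratum-dependent mark coverage, and a survival cohort whose hazard is
#' log-linear in standardized marker-gene expression.
#'
#' @param seed Integer seed; together with the config it fully determines
#'   every emitted object and file.
#' @param n_genes Number of genes on the synthetic chromosome.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp; \code{NULL} sizes it to fit
#'   the gene grid. Supplying a value too small for the grid is an error.
#' @param exons_per_gene Exons per gene (>= 1; introns require >= 2).
#' @param exon_length,intron_length Exon/intron sizes in bp.
#' @param gene_pitch Start-to-start spacing of consecutive genes in bp.
#' @param margin Gene-free margin at each chromosome end in bp.
#' @param n_peaks Named integer vector: peaks per category
#'   (\code{intronic}, \code{promoter}, \code{intergenic}).
#' @param occupancy_expression_slope Effect size coupling intronic peak
#'   amplitude to standardized log expression of the target gene (default
#'   0.5; 0 decouples them).
#' @param amp_base Baseline bump amplitude over background.
#' @param amp_noise Lognormal sd of intronic amplitude noise.
#' @param amp_sd_null Lognormal sd of promoter/intergenic amplitudes (drawn
#'   independent of expression).
#' @param target_enrichment Amplitude planted at the designated target
#'   gene's intronic peak (default 32, above the 16-fold high-stringency
#'   cut).
#' @param background Uniform background coverage per bp.
#' @param bump_sd Gaussian sd of each coverage bump in bp.
#' @param peak_halfwidth Half-width of emitted peak intervals in bp.
#' @param deg_counts Named vector: planted positively / negatively
#'   regulated gene counts.
#' @param fold_effect Planted fold change for DEGs (warn if not above
#'   \code{deg_fold_threshold}).
#' @param deg_fold_threshold Fold threshold the planted DEGs are meant to
#'   clear (the screen's default of 2).
#' @param noise_sd Lognormal sd of multiplicative expression noise.
#' @param baseline_meanlog,baseline_sdlog Lognormal baseline expression
#'   parameters.
#' @param mark_cooccupancy_probs Named probabilities that an intronic peak
#'   is co-occupied by each histone mark.
#' @param mark_halfwidth Half-width of mark peaks in bp.
#' @param turnover_frac Fraction of ChIP peaks lying in high-turnover
#'   regions.
#' @param turnover_halfwidth Half-width of turnover regions in bp.
#' @param stratum_active_marks,stratum_repressive_marks Mark names whose
#'   coverage is enriched in the high- (active) or low- (repressive)
#'   turnover stratum.
#' @param stratum_high_amp,stratum_low_amp Bump amplitudes for the enriched
#'   and depleted stratum respectively.
#' @param n_patients Cohort size (>= 4).
#' @param hazard_log_hr Named vector of log hazard ratios per standard
#'   deviation of log expression, one element per marker gene.
#' @param baseline_hazard Baseline exponential hazard rate.
#' @param censoring_rate Approximate fraction censored under the baseline
#'   hazard (uniform censoring horizon; 0 disables censoring).
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 1000,
                       chrom = "chrS",
                       chrom_length = NULL,
                       exons_per_gene = 3,
                       exon_length = 300,
                       intron_length = 1500,
                       gene_pitch = 12000,
                       margin = 20000,
                       n_peaks = c(intronic = 300, promoter = 300,
                                   intergenic = 300),
                       occupancy_expression_slope = 0.5,
                       amp_base = 6,
                       amp_noise = 0.2,
                       amp_sd_null = 0.5,
                       target_enrichment = 32,
                       background = 1,
                       bump_sd = 150,
                       peak_halfwidth = 400,
                       deg_counts = c(positive = 50, negative = 30),
                       fold_effect = 4,
                       deg_fold_threshold = 2,
                       noise_sd = 0.1,
                       baseline_meanlog = log(100),
                       baseline_sdlog = 1,
                       mark_cooccupancy_probs = c(H4K20me1 = 0.85,
                                                  H3K36me3 = 0.75,
                                                  H3K79me2 = 0.65,
                                                  H3K4me1 = 0.55,
                                                  H3K27me3 = 0.05),
                       mark_halfwidth = 300,
                       turnover_frac = 0.5,
                       turnover_halfwidth = 500,
                       stratum_active_marks = c("H2A.Z", "H3K4me1"),
                       stratum_repressive_marks = c("H3K9me3", "H3K27me3"),
                       stratum_high_amp = 10,
                       stratum_low_amp = 1,
                       n_patients = 200,
                       hazard_log_hr = c(H3F3A = log(3), GPR87 = log(3)),
                       baseline_hazard = 0.1,
                       censoring_rate = 0.3) {
  cfg <- as.list(environment())
  span <- gene_span_length(cfg)
  if (is.null(cfg$chrom_length)) {
    cfg$chrom_length <- 2L * margin + (n_genes > 0) *
      ((max(n_genes - 1L, 0L)) * gene_pitch + span)
    cfg$chrom_length <- as.integer(max(cfg$chrom_length, 2L * margin))
  }
  stopifnot(seed == as.integer(seed), n_genes >= 0, exons_per_gene >= 1,
            all(n_peaks >= 0), all(deg_counts >= 0),
            all(mark_cooccupancy_probs >= 0 & mark_cooccupancy_probs <= 1),
            turnover_frac >= 0, turnover_frac <= 1,
            censoring_rate >= 0, censoring_rate < 1,
            n_patients >= 4, background > 0, fold_effect > 1)
  if (!all(c("intronic", "promoter", "intergenic") %in% names(n_peaks))) {
    stop("n_peaks needs intronic, promoter and intergenic entries",
         call. = FALSE)
  }
  if (n_genes > 0 &&
      2 * margin + (n_genes - 1) * gene_pitch + span > cfg$chrom_length) {
    stop("genome too small: ", n_genes, " genes at pitch ", gene_pitch,
         " plus margins exceed chrom_length ", cfg$chrom_length,
         call. = FALSE)
  }
  if (gene_pitch < span) {
    stop("gene_pitch smaller than the gene span (overlapping genes)",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

gene_span_length <- function(cfg) {
  cfg$exons_per_gene * cfg$exon_length +
    max(cfg$exons_per_gene - 1L, 0L) * cfg$intron_length
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed ", x$seed, ", ", x$n_genes, " genes on ", x$chrom,
      " (", x$chrom_length, " bp), peaks ",
      paste(names(x$n_peaks), x$n_peaks, sep = "=", collapse = " "),
      ", ", x$n_patients, " patients\n", sep = "")
  invisible(x)
}

#' Simulate the synthetic genome
#'
#' Lays out \code{n_genes} non-overlapping genes on one chromosome at a
#' fixed pitch with alternating strands, each with \code{exons_per_gene}
#' equal exons separated by equal introns. Deterministic given the config.
#'
#' @param config A [sim_config()].
#' @return A [gene_models] object.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes == 0L) return(empty_gene_models())
  i <- seq_len(config$n_genes)
  gstart <- config$margin + (i - 1L) * config$gene_pitch + 1L
  span <- gene_span_length(config)
  gend <- gstart + span - 1L
  strand <- rep_len(c("+", "-"), config$n_genes)
  gid <- sprintf("G%04d", i)
  genes <- GenomicRanges::GRanges(
    config$chrom, IRanges::IRanges(gstart, gend), strand = strand
  )
  S4Vectors::mcols(genes)$gene_id <- gid
  pitch_in_gene <- config$exon_length + config$intron_length
  k <- seq_len(config$exons_per_gene) - 1L
  ex_start <- as.vector(outer(k * pitch_in_gene, gstart, `+`))
  ex <- GenomicRanges::GRanges(
    config$chrom,
    IRanges::IRanges(ex_start, width = config$exon_length),
    strand = rep(strand, each = config$exons_per_gene)
  )
  exons <- S4Vectors::split(ex, rep(gid, each = config$exons_per_gene))
  exons <- exons[gid]
  gene_models(genes, exons)
}

#' Write gene models as GTF
#'
#' Emits one \code{gene} line and one \code{exon} line per exon, 1-based
#' closed coordinates, with \code{gene_id}/\code{transcript_id} attributes.
#'
#' @param genes A [gene_models] object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gtf <- function(genes, path) {
  stopifnot(inherits(genes, "gene_models"))
  con <- file(path, "w")
  on.exit(close(con))
  g <- genes$genes
  for (i in seq_along(g)) {
    gid <- g$gene_id[i]
    ch <- as.character(GenomicRanges::seqnames(g))[i]
    st <- as.character(GenomicRanges::strand(g))[i]
    attr_g <- sprintf("gene_id \"%s\";", gid)
    attr_t <- sprintf("gene_id \"%s\"; transcript_id \"%s.1\";", gid, gid)
    writeLines(paste(ch, "irescreen", "gene", GenomicRanges::start(g)[i],
                     GenomicRanges::end(g)[i], ".", st, ".", attr_g,
                     sep = "\t"), con)
    ex <- genes$exons[[i]]
    for (j in seq_along(ex)) {
      writeLines(paste(ch, "irescreen", "exon", GenomicRanges::start(ex)[j],
                       GenomicRanges::end(ex)[j], ".", st, ".", attr_t,
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Simulate the overexpression/knockdown expression table
#'
#' Lognormal baseline intensities with multiplicative noise per condition;
#' planted positively regulated genes are multiplied by \code{fold_effect}
#' under overexpression and divided by it under knockdown, negatively
#' regulated genes the reverse. One planted positive gene is designated the
#' screen's unique intersection target.
#'
#' @param config A [sim_config()].
#' @param gene_id Optional gene ids (default those of [simulate_genome()]).
#' @return List with \code{table} (data frame: gene_id, control,
#'   overexpression, knockdown, knockdown_control) and \code{truth} (list:
#'   \code{positive}, \code{negative}, \code{target_gene}, \code{baseline}).
#' @export
simulate_expression <- function(config, gene_id = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(gene_id)) {
    gene_id <- sprintf("G%04d", seq_len(config$n_genes))
  }
  n <- length(gene_id)
  if (sum(config$deg_counts) > n) {
    stop("deg_counts exceed the number of genes", call. = FALSE)
  }
  if (config$fold_effect <= config$deg_fold_threshold) {
    warning("fold_effect <= deg_fold_threshold: planted DEG recovery is ",
            "not guaranteed", call. = FALSE)
  }
  set.seed(config$seed + 2L)
  base <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  planted <- sample(gene_id, sum(config$deg_counts))
  pos <- sort(planted[seq_len(config$deg_counts[["positive"]])])
  neg <- sort(setdiff(planted, pos))
  target <- if (length(pos) > 0L) pos[1L] else NA_character_
  noise <- function() exp(stats::rnorm(n, 0, config$noise_sd))
  oe_mult <- ifelse(gene_id %in% pos, config$fold_effect,
                    ifelse(gene_id %in% neg, 1 / config$fold_effect, 1))
  kd_mult <- ifelse(gene_id %in% pos, 1 / config$fold_effect,
                    ifelse(gene_id %in% neg, config$fold_effect, 1))
  table <- data.frame(
    gene_id = gene_id,
    control = base * noise(),
    overexpression = base * oe_mult * noise(),
    knockdown = base * kd_mult * noise(),
    knockdown_control = base * noise(),
    stringsAsFactors = FALSE
  )
  names(base) <- gene_id
  list(table = table,
       truth = list(positive = pos, negative = neg, target_gene = target,
                    baseline = base))
}

#' Simulate ChIP-seq peaks and coverage
#'
#' Places Gaussian-shaped coverage bumps over a uniform background: one
#' intronic peak (centered in the first intron) per selected gene, one
#' promoter peak just upstream of the TSS, and one intergenic peak in the
#' gene-free gap downstream of each selected gene. Intronic amplitudes are
#' coupled to target-gene expression as
#' \code{amp_base * exp(slope * z(log expr)) * exp(noise)}; promoter and
#' intergenic amplitudes are drawn independent of expression. Summits sit
#' at the bump maxima; the emitted enrichment is amplitude over background.
#' The designated target gene's intronic bump is planted at
#' \code{target_enrichment}. Genes without introns are skipped with a
#' message.
#'
#' @param config A [sim_config()].
#' @param genes A [gene_models] object from [simulate_genome()].
#' @param expression Named numeric vector of expression values per gene.
#' @param truth Optional DEG truth from [simulate_expression()]; planted
#'   DEG genes other than the target then receive no peaks, making the
#'   high-stringency nomination unique by construction.
#' @return List with \code{peaks} (a [peak_set()]), \code{track}
#'   (a [coverage_track()]) and \code{peak_truth} (data frame: name,
#'   category, gene, amplitude).
#' @export
simulate_chip <- function(config, genes, expression, truth = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(genes, "gene_models"))
  set.seed(config$seed + 3L)
  gid <- gene_ids(genes)
  target <- if (!is.null(truth)) truth$target_gene else NA_character_
  off_limits <- if (!is.null(truth)) {
    setdiff(c(truth$positive, truth$negative), target)
  } else {
    character(0)
  }
  eligible <- setdiff(gid, off_limits)
  introns <- gene_introns(genes)
  has_intron <- lengths(introns)[eligible] > 0L
  intron_pool <- eligible[has_intron]
  n_int <- config$n_peaks[["intronic"]]
  n_prom <- config$n_peaks[["promoter"]]
  n_inter <- config$n_peaks[["intergenic"]]
  if (any(!has_intron)) {
    message(sum(!has_intron), " gene(s) without introns skipped for ",
            "intronic peak placement")
  }
  pool <- setdiff(intron_pool, target)
  n_int_other <- min(n_int - as.integer(!is.na(target) && n_int > 0),
                     length(pool))
  int_genes <- sort(c(
    if (!is.na(target) && n_int > 0) target,
    sample(pool, n_int_other)
  ))
  rest <- setdiff(eligible, int_genes)
  prom_genes <- sort(sample(rest, min(n_prom, length(rest))))
  rest <- setdiff(rest, prom_genes)
  inter_genes <- sort(sample(rest, min(n_inter, length(rest))))

  gmap <- genes$genes
  idx <- function(g) match(g, gid)
  strand_of <- function(g) as.character(GenomicRanges::strand(gmap))[idx(g)]
  tss_of <- function(g) gmap$tss[idx(g)]

  # summit positions per category
  int_summit <- vapply(int_genes, function(g) {
    intr <- introns[[g]][1L]
    as.integer(floor((GenomicRanges::start(intr) +
                      GenomicRanges::end(intr)) / 2))
  }, integer(1))
  prom_summit <- vapply(prom_genes, function(g) {
    as.integer(tss_of(g) + ifelse(strand_of(g) == "+", -500L, 500L))
  }, integer(1))
  inter_summit <- vapply(inter_genes, function(g) {
    as.integer(GenomicRanges::end(gmap)[idx(g)] + 3000L)
  }, integer(1))

  # amplitudes
  z <- if (length(int_genes) > 1L) {
    as.numeric(scale(log(expression[int_genes])))
  } else {
    rep(0, length(int_genes))
  }
  a_int <- config$amp_base *
    exp(config$occupancy_expression_slope * z +
        stats::rnorm(length(int_genes), 0, config$amp_noise))
  if (!is.na(target)) {
    a_int[int_genes == target] <- config$target_enrichment
  }
  a_prom <- config$amp_base *
    exp(stats::rnorm(length(prom_genes), 0, config$amp_sd_null))
  a_inter <- config$amp_base *
    exp(stats::rnorm(length(inter_genes), 0, config$amp_sd_null))

  cat <- c(rep("intronic", length(int_genes)),
           rep("promoter", length(prom_genes)),
           rep("intergenic", length(inter_genes)))
  gene <- c(int_genes, prom_genes, inter_genes)
  summit <- c(int_summit, prom_summit, inter_summit)
  amp <- c(a_int, a_prom, a_inter)
  name <- paste0(substr(cat, 1, 3), "_", gene)

  track <- bump_track(config, summit, amp)
  peaks <- peak_set(
    chrom = config$chrom,
    start = pmax(1L, summit - config$peak_halfwidth),
    end = summit + config$peak_halfwidth,
    name = name, score = amp, enrichment = amp / config$background,
    summit = summit
  )
  list(peaks = peaks, track = track,
       peak_truth = data.frame(name = name, category = cat, gene = gene,
                               amplitude = amp, stringsAsFactors = FALSE))
}

# Gaussian bumps (rounded to integer counts) over a uniform background.
bump_track <- function(config, summits, amplitudes, background = NULL) {
  bg <- if (is.null(background)) config$background else background
  len <- config$chrom_length
  w <- as.integer(ceiling(4 * config$bump_sd))
  if (length(summits) > 0L) {
    offs <- -w:w
    dens <- exp(-(offs^2) / (2 * config$bump_sd^2))
    pos <- rep(summits, each = length(offs)) + offs
    val <- round(rep(amplitudes, each = length(offs)) * dens)
    keep <- pos >= 1L & pos <= len & val > 0
    ir <- IRanges::IRanges(start = pos[keep], width = 1L)
    cov <- IRanges::coverage(ir, weight = val[keep], width = len)
  } else {
    cov <- S4Vectors::Rle(0L, len)
  }
  cov <- cov + S4Vectors::Rle(as.integer(round(bg)), len)
  rl <- methods::as(stats::setNames(list(cov), config$chrom), "RleList")
  coverage_track(rl)
}

#' Simulate histone-mark peak sets, turnover regions and mark coverage
#'
#' Each mark co-occupies every intronic ChIP peak independently with its
#' configured probability (the enhancer mark H3K4me1, when configured, is
#' forced onto the planted target's peak so the co-occupancy funnel keeps
#' it). High-turnover regions cover a random fraction of all peaks; mark
#' coverage tracks for the configured active marks are amplified in the
#' high-turnover stratum and repressive marks in the low-turnover stratum.
#'
#' @param config A [sim_config()].
#' @param chip Result of [simulate_chip()].
#' @return List with \code{marks} (named list of \code{GRanges}),
#'   \code{turnover} (\code{GRanges}) and \code{mark_tracks} (named list of
#'   [coverage_track()]).
#' @export
simulate_marks <- function(config, chip) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  peaks <- chip$peaks
  tr <- chip$peak_truth
  int_idx <- which(tr$category == "intronic")
  int_summits <- peaks$summit[match(tr$name[int_idx], peaks$name)]
  target_row <- which(tr$category == "intronic" &
                      tr$amplitude >= config$target_enrichment)
  marks <- lapply(names(config$mark_cooccupancy_probs), function(m) {
    p <- config$mark_cooccupancy_probs[[m]]
    hit <- stats::runif(length(int_idx)) < p
    if (m == "H3K4me1" && length(target_row) > 0L) {
      hit[int_idx %in% target_row] <- TRUE
    }
    s <- int_summits[hit]
    gr <- GenomicRanges::GRanges(
      rep_len(config$chrom, length(s)),
      IRanges::IRanges(pmax(1L, s - config$mark_halfwidth),
                       s + config$mark_halfwidth)
    )
    S4Vectors::mcols(gr)$name <-
      if (length(gr)) paste0(m, "_", seq_along(gr)) else character(0)
    gr
  })
  names(marks) <- names(config$mark_cooccupancy_probs)

  n <- length(peaks)
  high <- sort(sample(n, round(config$turnover_frac * n)))
  s_all <- peak_reference_points(peaks)
  turnover <- GenomicRanges::GRanges(
    rep_len(config$chrom, length(high)),
    IRanges::IRanges(pmax(1L, s_all[high] - config$turnover_halfwidth),
                     s_all[high] + config$turnover_halfwidth)
  )
  S4Vectors::mcols(turnover)$name <-
    if (length(turnover)) paste0("turnover_", seq_along(turnover))
    else character(0)

  in_high <- seq_len(n) %in% high
  mk_track <- function(enrich_high) {
    amp <- ifelse(in_high == enrich_high, config$stratum_high_amp,
                  config$stratum_low_amp)
    bump_track(config, s_all, amp)
  }
  mark_tracks <- c(
    lapply(stats::setNames(config$stratum_active_marks,
                           config$stratum_active_marks),
           function(m) mk_track(TRUE)),
    lapply(stats::setNames(config$stratum_repressive_marks,
                           config$stratum_repressive_marks),
           function(m) mk_track(FALSE))
  )
  list(marks = marks, turnover = turnover, mark_tracks = mark_tracks)
}

#' Simulate a survival cohort
#'
#' Per-patient lognormal expression for each marker gene; exponential
#' survival with rate \code{baseline_hazard * exp(sum(log_hr * z))} where
#' \code{z} is the patient's standardized log expression; independent
#' uniform censoring horizon calibrated so that roughly
#' \code{censoring_rate} of baseline-hazard patients are censored. The
#' relapse flag is \code{"yes"} for patients whose event was observed.
#'
#' @param config A [sim_config()].
#' @return List with \code{cohort} (data frame: patient_id, one expression
#'   column per marker gene, time, event, relapse) and \code{truth} (list
#'   with the per-patient true hazard \code{rate}).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 5L)
  n <- config$n_patients
  genes <- names(config$hazard_log_hr)
  expr <- lapply(genes, function(g) {
    stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  })
  names(expr) <- genes
  z <- vapply(expr, function(e) as.numeric(scale(log(e))),
              numeric(n))
  lp <- as.numeric(z %*% config$hazard_log_hr)
  rate <- config$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n, rate)
  if (config$censoring_rate > 0) {
    horizon <- censoring_horizon(config$baseline_hazard,
                                 config$censoring_rate)
    c_time <- stats::runif(n, 0, horizon)
  } else {
    c_time <- rep(Inf, n)
  }
  time <- pmin(t_event, c_time)
  event <- as.integer(t_event <= c_time)
  cohort <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                       stringsAsFactors = FALSE)
  for (g in genes) cohort[[g]] <- expr[[g]]
  cohort$time <- time
  cohort$event <- event
  cohort$relapse <- ifelse(event == 1L, "yes", "no")
  list(cohort = cohort, truth = list(rate = rate))
}

# Horizon tau with P(censored) = (1 - exp(-lambda*tau)) / (lambda*tau)
# equal to the requested rate under the baseline hazard.
censoring_horizon <- function(lambda, rate) {
  f <- function(tau) (1 - exp(-lambda * tau)) / (lambda * tau) - rate
  stats::uniroot(f, lower = 1e-9, upper = 1e9, tol = 1e-9)$root
}

#' Simulate the full synthetic study
#'
#' Runs the generator stages on substreams derived from the config seed
#' (genome, expression, ChIP, marks, cohort), so each stage is individually
#' reproducible, and optionally writes all inputs as standard-format files.
#'
#' @param config A [sim_config()].
#' @param outdir Optional directory; when given, writes \code{genes.gtf},
#'   \code{chip.narrowPeak}, \code{chip.bedGraph}, \code{marks/<mark>.bed},
#'   \code{turnover.bed}, \code{expr.tsv}, \code{cohort.tsv} and
#'   \code{truth.json}.
#' @return An object of class \code{ire_study}: list with \code{config},
#'   \code{genes}, \code{expression}, \code{peaks}, \code{track},
#'   \code{marks}, \code{turnover}, \code{mark_tracks}, \code{cohort} and
#'   \code{truth}.
#' @export
simulate_study <- function(config = sim_config(), outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genes <- simulate_genome(config)
  expr <- simulate_expression(config, gene_id = gene_ids(genes))
  expression_values <- stats::setNames(expr$table$control,
                                       expr$table$gene_id)
  chip <- simulate_chip(config, genes, expression_values,
                        truth = expr$truth)
  marks <- simulate_marks(config, chip)
  cohort <- simulate_cohort(config)
  truth <- list(
    positive = expr$truth$positive,
    negative = expr$truth$negative,
    target_gene = expr$truth$target_gene,
    peak_truth = chip$peak_truth,
    cohort_rate = cohort$truth$rate
  )
  study <- structure(
    list(config = config, genes = genes, expression = expr$table,
         peaks = chip$peaks, track = chip$track, marks = marks$marks,
         turnover = marks$turnover, mark_tracks = marks$mark_tracks,
         cohort = cohort$cohort, truth = truth),
    class = "ire_study"
  )
  if (!is.null(outdir)) write_study(study, outdir)
  study
}

#' @export
print.ire_study <- function(x, ...) {
  cat("ire_study: ", length(x$genes), " genes, ", length(x$peaks),
      " peaks, ", nrow(x$expression), " expression rows, ",
      nrow(x$cohort), " patients (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a simulated study to standard-format files
#'
#' @param study An [simulate_study()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, \code{outdir}.
#' @export
write_study <- function(study, outdir) {
  stopifnot(inherits(study, "ire_study"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "marks"), showWarnings = FALSE)
  write_gtf(study$genes, file.path(outdir, "genes.gtf"))
  write_peaks(study$peaks, file.path(outdir, "chip.narrowPeak"))
  write_coverage(study$track, file.path(outdir, "chip.bedGraph"))
  for (m in names(study$marks)) {
    write_bed(study$marks[[m]], file.path(outdir, "marks", paste0(m, ".bed")))
  }
  write_bed(study$turnover, file.path(outdir, "turnover.bed"))
  write_tsv_table(study$expression, file.path(outdir, "expr.tsv"))
  write_tsv_table(study$cohort, file.path(outdir, "cohort.tsv"))
  truth <- study$truth
  truth$cohort_rate <- as.numeric(truth$cohort_rate)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
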