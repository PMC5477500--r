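# irescreen

An R package implementing an integrative epigenomic screen for **intronic
regulatory elements (IREs)** occupied by the histone variant **H3.3** — the
analysis style used to show that *H3F3A* overexpression activates
metastasis-related genes in lung cancer through intronic deposition, and to
nominate *GPR87* as a direct target whose expression, alone or combined
with *H3F3A*, stratifies patient survival.

It is aimed at computational biologists who have peak calls, coverage
tracks, gene models, overexpression/knockdown expression tables and a
clinical cohort, and want to run (or study) the full nomination funnel
offline and reproducibly.

## What the screen computes

* **Peak annotation.** Every base is labeled under the priority
  promoter > exon > intron > intergenic (promoter window −2000/+500 bp
  around the TSS, strand-oriented); a peak's category is the label at its
  summit, and its target gene is the nearest gene within 10 kb.
* **Stringency funnels.** Low stringency keeps the top n = 3000 peaks by
  caller score; high stringency keeps peaks with log2(ChIP/input) ≥ 4
  (ratio ≥ 16).
* **Occupancy-expression profiles.** Summit-centered binned occupancy,
  RPKM = count / (bin kb) / (library millions), rows sorted by target-gene
  expression and grouped into tertiles; group averages smoothed by lowess
  (tricube local linear regression, span f = 0.3). The screen's signature:
  intronic occupancy correlates with expression, promoter/intergenic does
  not.
* **Chromatin context.** Fraction of peaks co-occupied (≥1 bp overlap) by
  each histone-mark peak set, and mark occupancy compared between high- and
  low-nucleosome-turnover strata (rank-sum statistic on ±1 kb mean RPKM).
* **DEG rule.** A gene is a DEG when it moves in opposite directions under
  overexpression and knockdown and exceeds 2-fold in at least one of the
  two contrasts; positive = up under overexpression.
* **Nomination.** Direct-target candidates are the exact intersection of
  the ChIP-derived target-gene set (optionally restricted to
  mark-co-occupied intronic peaks) with the DEG set.
* **Survival.** Median-split and dual-gene four-group stratification,
  Kaplan-Meier curves, log-rank tests, and Welch t comparison of relapsed
  versus non-relapsed patients.

A seeded synthetic-data generator (`simulate_study()`) emits
GTF/narrowPeak/bedGraph/TSV inputs with planted ground truth — occupancy
coupled to expression only in introns, planted opposite-direction DEGs, a
unique planted intersection target, and cohorts with known hazard ratios —
so every stage is testable with no external data.

## Worked example

```r
library(irescreen)

# Printed reporter-element coordinates (1-based, closed; commas accepted)
ire     <- parse_region_string("chr3:151,022,847-151,023,000")
non_ire <- parse_region_string("chr3:151,024,703-151,024,854")
GenomicRanges::width(c(ire, non_ire))   # 154 152
region_separation(ire, non_ire)         # 1703

# A fully synthetic study with exposed ground truth
study <- simulate_study(sim_config(seed = 1))
#> ire_study: 1000 genes, 900 peaks, 1000 expression rows, 200 patients (seed 1)

fmap <- build_feature_map(study$genes)
ann  <- annotate_peaks(study$peaks, fmap, study$genes)
round(genomic_distribution(ann), 3)
#>   promoter       exon     intron intergenic
#>      0.333      0.000      0.333      0.333

# Intronic occupancy tracks target-gene expression
expr <- setNames(study$expression$control, study$expression$gene_id)
pm   <- sort_rows_by_expression(
          profile_matrix(ann[ann$category == "intron"], study$track), expr)
cor.test(rowMeans(pm$values, na.rm = TRUE), pm$row_meta$expression,
         method = "spearman", exact = FALSE)
#> rho = 0.915, p = 2.3e-119          (promoter/intergenic: |rho| ~ 0)

# Opposite-direction DEGs and target nomination
degs <- select_degs(study$expression)
degs
#> deg_result: 50 positively / 30 negatively regulated genes
#> (either contrast > 2-fold, opposite directions)
hs  <- filter_high_stringency(ann)             # log2(ChIP/input) >= 4
nominate_targets(unique(hs$target_gene[!is.na(hs$target_gene)]),
                 c(degs$positive, degs$negative))
#> "G0004"    -- exactly the planted target (study$truth$target_gene)

# Expression-stratified survival
grp <- split_by_expression(study$cohort, "H3F3A")
logrank(study$cohort$time, study$cohort$event, grp)$p_value
#> 3.4e-07
```

The numbers mean: peaks split evenly over the three planted categories (no
exonic peaks are planted); the planted occupancy-expression coupling is
recovered only in introns; the DEG rule recovers exactly the 50 + 30
planted genes; the high-stringency ∩ DEG intersection contains exactly the
planted target; and the cohort's planted hazard ratio of 3 per SD of log
expression yields a strongly significant median-split log-rank test.

A thin CLI over the same functions is installed at
`inst/cli/ire-screen.R` (`convert-region`, `validate`, `annotate`,
`filter`, `degs`, `nominate`, `survival`, `simulate`).

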