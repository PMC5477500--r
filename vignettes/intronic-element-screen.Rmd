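---
title: "Screening for histone-variant-occupied intronic regulatory elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for histone-variant-occupied intronic regulatory elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screen

The histone variant H3.3 (encoded by *H3F3A*) is deposited
replication-independently and marks active chromatin. When it accumulates in
the *intron* of a gene, the occupied element can behave like an intronic
regulatory element (IRE): an enhancer-like sequence inside the gene body that
modulates its host gene's transcription. `irescreen` implements the
integrative screen that nominates such elements and their target genes from
four kinds of evidence:

1. **Where the peaks are.** ChIP-seq peaks are annotated by genomic feature
   (promoter / exon / intron / intergenic) at their summit position, and each
   peak is assigned the nearest gene within 10 kb as its putative
   cis-regulatory target.
2. **Whether occupancy tracks expression.** Summit-centered, binned RPKM
   occupancy profiles are related to target-gene expression. The screen's
   key qualitative signature is that *intronic* occupancy correlates
   positively with target-gene expression while promoter and intergenic
   occupancy do not.
3. **What chromatin the peaks sit in.** Co-occupancy with histone-mark peak
   sets (gene-body marks, the enhancer mark H3K4me1, repressive marks) and
   with high nucleosome-turnover regions distinguishes regulatory-element
   chromatin from bulk gene body.
4. **Whether the target gene responds.** Genes changing more than 2-fold in
   *opposite directions* under overexpression versus knockdown of the
   histone-variant gene are called DEGs; intersecting the ChIP-derived gene
   set with the DEG set nominates direct targets.

A final clinical module stratifies patient cohorts by marker-gene expression
(median split, or the cross of two splits) and compares survival with the
Kaplan-Meier estimator and the log-rank test, and relapse groups with
Welch's t-test.

## Coordinate conventions

All intervals are held as `GRanges`, i.e. 1-based with closed ends — the
same convention as printed genome-browser coordinates and GTF. The parsers
own every conversion: BED, narrowPeak and bedGraph inputs (0-based,
half-open) are shifted on read and shifted back on write; narrowPeak summit
offsets become absolute 1-based summit positions. `parse_region_string()`
accepts printed coordinates with thousands separators, so the worked
example

```{r}
library(irescreen)
ire     <- parse_region_string("chr3:151,022,847-151,023,000")  # 154 bp
non_ire <- parse_region_string("chr3:151,024,703-151,024,854")  # 152 bp
region_separation(ire, non_ire)                                 # 1703
```

reproduces the printed element lengths exactly. `region_separation()`
measures the printed-coordinate offset `start(downstream) − end(upstream)` —
the convention in which an element "1,703 bp upstream" of another is
separated by 1,703 — which is one more than the count of bases strictly
between the intervals. Nearest-gene distances, by contrast, use the
strictly-between count (`GenomicRanges::distance()` semantics), with 0 for
overlapping or abutting intervals. Chromosome names match as exact strings;
there is no "chr" aliasing.

## Feature labeling and target assignment

`build_feature_map()` labels every base with exactly one of
promoter > exon > intron > intergenic, the priority applying across all
overlapping genes, so a neighbouring gene's promoter window masks another
gene's exon. The promoter window defaults to (−2000, +500) bp around the
TSS, oriented by strand — a common convention, exposed as a knob since the
underlying analysis does not pin it down. Peak category is decided by the
label at the *summit* (single-point rule; the midpoint is used when the
caller reported no summit, and a `rule = "midpoint"` option forces it).
Target assignment measures peak-boundary to gene-span-boundary distance,
keeps genes within `max_dist = 10000` bp, and breaks exact ties by smaller
gene start then lexicographic gene id, so results are independent of gene
insertion order.

## Stringency funnel

Two cutoffs mirror the screen's two funnels: `select_top_peaks()` keeps the
n = 3000 highest caller scores (low stringency), and
`filter_high_stringency()` keeps peaks with log2(ChIP/input) ≥ 4, i.e. a
16-fold ratio. The boundary value 16 is *retained*: the log-scale statement
of the rule is inclusive while the prose ">16" is strict, and we resolve
the measure-zero disagreement in favour of the inclusive log-scale form,
with a `strict = TRUE` flag for the other reading.

## Occupancy profiles

`profile_matrix()` bins the ±`flank` window around each summit
(default ±2 kb in 20-bp bins; 10-bp bins and ±5 kb windows are knobs) and
computes per-bin RPKM = count / (bin kb) / (library millions), where count
is the *summed per-base coverage* in the bin (fragment-depth semantics; the
generator emits matching semantics, and read-5′-end counting would simply
rescale). Windows that would run off the chromosome start keep their rows,
with out-of-genome bins masked as `NA` and excluded from group means. The
conservation identity — summing RPKM × bin-kb × library-millions recovers
the raw window count exactly — is asserted in the tests.

Rows are sorted by descending target-gene expression
(`sort_rows_by_expression()`), grouped into equal-count tertiles by rank
(`expression_groups()`; ties resolve stably, extra members go to the low
then intermediate group), and per-group average profiles are smoothed with
`lowess_smooth()`: local linear regression at each bin with tricube
weights over the `ceiling(f * n)` nearest bins, `f = 0.3`, and zero
robustness iterations so the output is deterministic. This is the classical
lowess smoother; the package carries its own implementation because the
span rule and iteration count are pinned down here, and the tests verify it
both against a directly-summed local regression oracle (to 1e-8) and
against `stats::lowess` where the two span rules coincide.

## Co-occupancy and turnover strata

`overlap_fraction()` counts a query peak as co-occupied when it shares at
least 1 bp with any mark peak (the minimum overlap is configurable);
`rank_marks()` orders mark sets by that fraction. `stratify_by_turnover()`
partitions peaks by ≥1 bp overlap with high-turnover regions (supplied as
intervals; estimating turnover from raw time courses is out of scope), and
`mark_occupancy_by_stratum()` compares whole-window (±1 kb) mean RPKM per
mark between strata with a Wilcoxon rank-sum statistic. The rank-sum test
is descriptive — the underlying comparison is a boxplot-level contrast, and
no particular test is canonical for it — so the whole-window mean (no inner
binning) is used as the per-peak summary.

## DEG rule and nomination

`select_degs()` reads the rule "greater than 2-fold in either contrast,
opposite responses in both" literally: direction must oppose in *both*
contrasts (up under overexpression and down under knockdown, or vice
versa), and the 2-fold threshold must be met in *at least one* contrast.
The stricter both-contrasts-thresholded variant is available as
`both_contrasts = TRUE`. Knockdown folds use the dedicated
`knockdown_control` column when present, else the shared control. No
significance filter is applied — the rule is fold-change-only.
`rank_degs()` (the low-stringency "top 3000 probes" funnel) ranks
opposite-direction probes by the larger absolute log2 fold of the two
contrasts, a documented choice since the original ranking key is not
specified. `nominate_targets()` is the exact set intersection of the ChIP
and DEG funnels, and `genes_with_cooccupied_introns()` restricts the ChIP
funnel to genes whose intronic peaks overlap a mark peak set.

## Survival analysis

`split_by_expression()` dichotomizes at the cohort median with the median
itself assigned to "low" (only "higher/lower" grouping is specified
upstream; the quantile is configurable). `four_group_stratify()` crosses
two median splits. The Kaplan-Meier estimator and log-rank test are
delegated to the survival package (`survfit`/`survdiff`) behind the module
surface, with tied event times handled by the standard aggregated-risk-set
formulation; tests verify both against hand-computed product-limit examples
and a textbook observed-minus-expected oracle. Multivariate Cox modelling
is intentionally excluded — it is off-the-shelf statistics on external
data — but the cohort tables the generator emits are directly consumable by
`survival::coxph`.

## The synthetic study

`simulate_study()` generates every input the screen consumes, with ground
truth exposed, so the whole pipeline is testable without any external
download. What it emulates, and what it deliberately does not:

* **Genome** (`simulate_genome`): 1000 genes on one chromosome at a fixed
  12-kb pitch with alternating strands, three 300-bp exons separated by
  1.5-kb introns. Real gene models vary in size and overlap; the grid keeps
  every feature class well populated and unambiguous.
* **ChIP** (`simulate_chip`): Gaussian coverage bumps (sd 150 bp) over a
  uniform background of 1, at 300 intronic, 300 promoter and 300 intergenic
  sites. Intronic amplitudes follow
  `6 · exp(0.5 · z(log expr) + N(0, 0.2))`; promoter/intergenic amplitudes
  are drawn independently of expression (`6 · exp(N(0, 0.5))`). The planted
  target gene's intronic bump is fixed at 32× background so it clears the
  16-fold cut. Coverage is emitted at 1-bp resolution so the RPKM
  conservation identity is exact. There is no read-level noise model, GC
  bias or mappability structure.
* **Expression** (`simulate_expression`): lognormal baselines
  (meanlog log 100, sdlog 1), multiplicative lognormal noise (sd 0.1) per
  condition, 50 planted positive and 30 negative DEGs at fold 4 — strong
  enough that exact recovery is expected at these settings, which is the
  point: the test isolates the selection rule, not array noise modelling.
  Planted DEG genes other than the target receive no ChIP peaks, making the
  high-stringency nomination unique by construction.
* **Marks and turnover** (`simulate_marks`): each mark co-occupies intronic
  peaks independently with its configured probability (defaults descending
  from 0.85 for gene-body marks to 0.05 for the repressive mark), H3K4me1
  is forced onto the target's peak, and turnover regions cover a random
  half of all peaks with active-mark coverage 10× in the high-turnover
  stratum (repressive marks reversed).
* **Cohort** (`simulate_cohort`): 200 patients, exponential survival with
  rate `0.1 · exp(Σ log HR · z(log expr))`, default log HR = log 3 for each
  of two independent marker genes, uniform censoring horizon calibrated to
  censor roughly 30% at baseline. Real cohorts have correlated markers and
  non-exponential hazards; the generator trades that realism for an exact,
  seedable null and alternative.

Each stage runs on its own substream derived from the config seed
(fixed offsets), consumed in the order genome → expression → ChIP → marks →
cohort, so identical configs give byte-identical output files and any
prefix of stages can be regenerated alone.

Because the planted structure is strong, a passing suite demonstrates that
the *rules* are implemented correctly and recover known structure; it does
not demonstrate robustness to the noise levels, batch effects or annotation
ambiguity of real data.

## Problem sizes and seeds

The reference study conditions are the generator defaults above: 300
profile rows per feature class for the occupancy-expression contrast, 1000
genes for DEG recovery, 200 patients per cohort, 200 replicate cohorts for
log-rank power (hazard ratio 3) and null calibration. These sizes make all
planted effects detectable at conventional thresholds while keeping a full
run in the order of a minute. All randomness flows through explicit seeds;
the test suite freezes its seeds, and `scripts/acceptance.R` derives every
stream from its `--seed` argument.

## Known limitations

* Headline counts from the motivating study (871 high-stringency peaks,
  the 56%/39% intergenic/intronic split, the 2392/787/366/29 gene funnel,
  112/70 DEGs, cohort p-values) depend on its external sequencing, array
  and cohort data and are not reproduced here; the package reproduces the
  *rules and qualitative signatures* on synthetic data instead.
* Annotation is gene-level: no transcript isoforms, UTR subcategories or
  enhancer calling.
* Coverage input is bedGraph only (no BAM/bigWig); peak calling and read
  alignment are upstream of the package.
* Whether peaks should be annotated by summit or by any-overlap, and
  whether the 10-kb rule should measure to gene bodies or TSSs, are not
  settled by the source analysis; the defaults (summit; gene bodies) are
  exposed as options.
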