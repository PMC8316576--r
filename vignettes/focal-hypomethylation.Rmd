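---
title: "Calling canonical focal hypomethylation and linking it to expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling canonical focal hypomethylation and linking it to expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalmeth)
```

## The phenotype and the model

Reduced DNMT3A activity — whether from simple haploinsufficiency or from a
dominant-negative R882/R878H protein that traps its wild-type partner in
inactive heterodimers — produces *focal, canonical hypomethylation* in
blood cells: discrete regions of roughly 600–900 bp lose methylation while
global methylation stays near normal. "Canonical" means the loss is
reproducible across carriers rather than driven by outlier samples; the
depth of the loss tracks the severity of the functional deficit
(dominant-negative ≫ haploinsufficient, with full knockout deepest of
all).

`focalmeth` operationalizes this as a region-calling problem on per-CpG
WGBS tables (methylated/unmethylated counts per strand-collapsed CpG).
The caller is a four-stage cascade whose published acceptance thresholds
are applied verbatim downstream of a transparent segmentation:

1. **Segmentation** (`segment_candidates`). A greedy left-to-right
   seed-and-extend scan over CpGs in coordinate order. A candidate is a
   maximal run in which every CpG is covered in at least 2 samples per
   group, consecutive CpGs are at most 300 bp apart (the conventional
   neighborhood radius for WGBS segmentation), the per-CpG group-mean
   difference keeps one sign, the running mean of the difference stays at
   or above 0.2 in absolute value, and the run holds at least 10 CpGs.
   This is a deliberate substitute for metilene-style segmentation: that
   tool's internal two-dimensional Kolmogorov–Smirnov recursion resists
   hand-verification, while this scan is enumerable and testable by
   tracing, and all the acceptance thresholds below are independent of
   the segmenter.
2. **Scoring** (`score_and_filter`). Per-sample regional means are the
   unweighted mean of that sample's covered CpG ratios in the region
   (coverage weighting is available but off by default — the ratio, not
   the read count, is the quantity of interest). The region test is an
   exact two-sided Mann–Whitney U on per-sample regional means (exact
   enumeration-equivalent null for group sizes ≤ 8 without ties; mid-rank
   normal approximation with continuity correction otherwise).
   Benjamini–Hochberg q-values are computed across *all* candidates
   genome-wide; survivors need q ≤ 0.05 and |Δm̄| ≥ 0.2.
3. **Merging** (`merge_adjacent`). Same-chromosome records separated by
   strictly less than 50 bp merge transitively. Merged records are new
   hypotheses: all statistics are recomputed over the union of member
   CpGs and BH is re-run on the post-merge set — the conservative choice,
   recorded in the output metadata.
4. **Canonicality** (`canonicality_filter`). A record survives only if
   the SD of per-sample regional means is ≤ 0.1 — inclusive — in *both*
   groups (a switch restricts this to the test group). Groups with fewer
   than two samples have undefined SD; such records are kept but flagged.

All thresholds are inclusive (≥ 10 CpGs, ≥ 0.2, ≤ 0.05, ≤ 0.1); where
exclusive readings of the CpG-count and difference rules circulate, the
inclusive reading is the weaker, documented choice. The caller is fully
deterministic.

One deliberate sharp edge: a CpG that fails the per-group coverage
minimum *breaks* a run (runs are defined over consecutive CpGs that each
pass). At ~18x coverage with ≥ 2 covered samples required per group this
is rare, and the subsequent < 50 bp merge re-joins fragments split by an
isolated dropout; both behaviors are exercised in the tests.

## Covariates, QC, and summaries

Because methylation drifts with age and differs by sex, every called DMR
is re-checked by OLS of the per-sample regional mean on a genotype
indicator, a sex indicator, and log(age) (`covariate_regression`), with a
two-sided t-test on the genotype coefficient and BH across DMRs. Designs
where sex or age is confounded with genotype are flagged singular rather
than silently dropped. Replicate quality is summarized as within-group
pairwise Pearson correlations over co-covered CpGs
(`replicate_correlation`), flagged when any pair falls to r ≤ 0.8 — the
conventional reproducibility bar for WGBS biological replicates.
`dmr_summary` reports counts, width mean ± SD, and — when comparing two
record sets — a pooled-variance two-sample t-test on widths computed from
summary statistics (`t_test_from_summary`), plus ≥ 1 bp intersection
counts in both scanning directions.

## Annotation enrichment and cross-genome correspondence

Overlap semantics are uniform everywhere: half-open intervals, "contains"
and "direct correspondence" mean at least 1 shared bp, and proximity is
edge-to-edge distance with overlap counting as 0. The enrichment test for
"fraction of features containing ≥ 1 DMR" is a pairwise 2×2 chi-squared
without continuity correction, switching to Fisher's exact test when any
expected cell is below 5 — the standard switch rule, recorded per pair. One boundary case is documented rather than hidden: two intervals
that touch without sharing a base ([a,b) and [b,c)) have edge distance 0
but do not correspond directly, so "within 0 bp" can exceed "direct" on
exactly-adjacent pairs.

Liftover (`read_chain`, `liftover_interval`) walks UCSC chain files
directly: bases are mapped through the aligned blocks of the best-scoring
overlapping chain, minus-strand chains reverse correctly, and every
failure is a status, not an error — `unmapped` (no base maps), `split`
(the best chain maps too little while another maps part of the interval),
`low_ratio` (mapped fraction below a permissive, configurable 0.5
default, recorded in output). Correspondence percentages divide by the *full*
source set, unmapped intervals included — the arithmetic that reproduces
the reported cross-species percentages — and
`bidirectional_comparison` reports both directions without reconciling
their expected asymmetry.

## Single-cell integration

QC removes cells with fewer than 250 expressed genes, less than 500 total
reads, or more than 10% mitochondrial transcripts — strict inequalities
exactly as worded, so boundary cells survive; the tests pin this.
Normalization scales each cell to exactly 10,000 reads before log1p
(natural log, the dominant single-cell convention; configurable). Per-cluster
differential expression uses a Welch two-sided t-test on log-normalized
values: for a two-condition contrast a one-way ANOVA F reduces to t², and
Welch guards against unequal variances. The fold-change gate uses depth-scaled
(pre-log) group means with a pseudo-count of 1. Both gates — p ≤ 0.05 and
|log2 ratio| ≥ 1 — are conjunctive, with no multiple-testing correction in
the gate itself (a BH column is emitted for users). Clustering is an
input, not a computation: labels come with the matrix, and lineage
annotation (`knn_lineage_annotate`) is nearest-centroid Spearman
correlation against reference expression profiles, ties broken by higher
mean correlation, undefined correlations labeled `unassigned`. DEG↔DMR
linking measures gene-body edge distance with a 10 kb radius; the
anchor (gene body rather than TSS or promoter) is configurable.

## What the generator emulates — and what it does not

The synthetic module (`sim_config`, `simulate_genome_cpgs`,
`simulate_methylation_samples`, `simulate_chain_pair`, `simulate_scrna`)
states a world and sticks to it:

- **Genome**: 3 chromosomes × 2 Mb; CpG islands every 50 kb (1 kb wide,
  ~12 bp CpG spacing, baseline methylation ≈ 0.1) on a hypermethylated
  background (≈ 0.9) with ~55 bp mean CpG spacing, so that a median
  ~650 bp region holds ≥ 10 CpGs — focal hypomethylation in this disease
  context lives in CpG-dense methylated sequence, and placement requires
  at least 12 background CpGs per planted region.
- **Planted regions**: 50 focal regions (plus knockout-only extras and
  optional age-effect regions), widths lognormal around a ~650 bp median,
  60% inside gene bodies (the annotations are written accordingly). Each
  region carries a depth factor ~ Lognormal(0, 0.45) multiplying the tier
  effect (severe −0.35, mild −0.12, haploinsufficient −0.03, knockout
  −0.55). The depth factor is what makes the tiers behave like the
  reported inventories at desk scale: nearly all severe-tier regions
  clear the 0.2 difference threshold, a minority of mild-tier regions do,
  and essentially no haploinsufficient ones — the severe ≫ mild ≫ haplo
  count ordering is then a property of the stated world, not a tuned
  outcome.
- **Noise**: per-sample beta jitter with concentration 200 (regional SD
  ≈ 0.03, comfortably canonical) except in a 5% "noisy region" fraction
  (concentration 12, SD ≈ 0.2) planted to exercise the canonicality
  filter; coverage ~ NegBin(mean 18, size 8); methylated counts binomial.
- **Cohorts**: 6 vs 10 by default (mouse-like), ages log-uniform on
  [2, 43], sexes alternating; human-like designs (3 vs 15, 8 vs 15) are a
  config change.
- **Chains**: the second genome is a block permutation (50 kb blocks) of
  the first with configurable inversion and deletion fractions; valid
  chain files are emitted in both directions together with a truth table
  for every planted region.
- **scRNA**: 4 clusters × 150 cells per sample × 2 samples, 600 genes,
  disjoint marker blocks (8-fold), 5 planted DEGs per cluster (4-fold) in
  the mutant genotype, ~5% mitochondrial genes with a per-cell mito load
  whose tail crosses the 10% bar, and a 2% fraction of deliberately
  QC-failing cells.

Ground truth is emitted beside the data and never consumed by the
pipeline. Everything derives from one seed; identical configs produce
byte-identical files.

What the generator does **not** emulate: real CpG density heterogeneity
(shores, shelves, repeats), bisulfite non-conversion and mapping bias,
batch and cell-composition effects in bulk ratios, doublets and ambient
RNA in single-cell counts, and real synteny structure (chains here are
block permutations, not evolutionary alignments). A green recovery test
therefore establishes that the caller detects focal, canonical signals of
the stated depth under honest sampling noise — not that it would match any
particular real cohort's inventory.

## Numerical choices

- Missing data: an uncovered CpG is missing, never zero; all means skip
  missing values. Ratio validation on input tolerates 0.01 absolute
  (printed rounding).
- Exact MWU switches to the normal approximation on ties or group sizes
  over 8; BH is `stats::p.adjust`; both are verified against brute-force
  enumeration/definition oracles in the test suite, at every use.
- Chi-squared tests are Pearson without continuity correction (verified
  against the textbook formula); Fisher's exact is used for small
  expected counts and verified against hypergeometric enumeration.
- The BED score encodes round(1000·|Δm̄|) capped at 1000; TSV output
  round-trips records bit-exactly.
- Degenerate inputs are contracts, not crashes: empty files give empty
  containers, empty region sets give zero counts and p = 1 where a test
  is defined, groups that lose all samples drop the candidate with a
  warning, and singular regression designs are flagged.

## Limitations

The segmentation is a documented substitute, not a reconstruction of
metilene; region boundaries can differ from that tool's even when the
downstream criteria agree. The greedy scan is order-deterministic but not
globally optimal — a long run that dips below the running-mean threshold
closes rather than back-tracking. Width statistics are computed on the
final (post-SD-filter) record set. The liftover handles the chain format
fully but chooses a single best chain per interval rather than stitching
across chains; split mappings count as unmapped in correspondence
percentages, a documented convention rather than a reconstruction of any
particular liftOver parameterization.
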