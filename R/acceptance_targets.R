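# ---------------------------------------------------------------------------
# Worked examples at reported scale. The full-scale DMR inventories these
# summaries come from (controlled-access human WGBS, large mouse cohorts)
# are not reproducible at desk scale; what IS checkable is the arithmetic
# that turns the reported inventory counts into the reported fractions,
# percentages, and the width t-test. Each builder below constructs interval
# or record sets realizing the printed counts and runs the package's own
# operations on them, so the reported quantities are recomputed, not
# transcribed.
# ---------------------------------------------------------------------------

# n regularly spaced intervals, far enough apart that constructions cannot
# contaminate each other's neighborhoods.
lattice_regions <- function(n, width = 600L, spacing = 50000L,
                            chrom = "chr1", offset = 0L) {
  start <- offset + spacing * (seq_len(n) - 1L)
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + width))
}

#' Recompute the reported worked-example quantities
#'
#' Reconstructs each reported summary from its input counts and runs the
#' corresponding package operation on it:
#' \describe{
#'   \item{t1}{percent of 18,951 human gene bodies containing at least one
#'     of 1,426 DMR-hit features (via \code{\link{features_containing_dmrs}}).}
#'   \item{t2}{same for 22,026 mouse gene bodies with 1,375 hits.}
#'   \item{t3}{percent of the 332 non-R882 DMRs overlapping (>= 1 bp) the
#'     2,209 R882 DMRs when 215 pairs overlap
#'     (\code{\link{compare_dmr_sets}}).}
#'   \item{t4}{the same 215 overlaps as a percent of the R882 set.}
#'   \item{t5, t6}{percent of 2,209 human DMRs with direct (101) and
#'     within-10 kb (1,713) mouse correspondence.}
#'   \item{t7, t8}{the reverse direction: 95 direct and 1,889 proximal of
#'     2,172 mouse DMRs.}
#'   \item{t9}{two-tailed pooled-variance t-test p comparing DMR widths
#'     from summary statistics (662.7 +/- 441.6, n = 2209 vs
#'     614.5 +/- 366.8, n = 332) via \code{\link{t_test_from_summary}}.}
#'   \item{t10}{percent of 242 human DEG genes with concordant mouse
#'     dysregulation when 121 symbols match
#'     (\code{\link{cross_species_deg_concordance}}).}
#'   \item{t11}{count of the 242 DEG genes whose gene body lies within
#'     10 kb of a DMR when 38 do (\code{\link{link_degs_to_dmrs}}).}
#' }
#'
#' @return named list of numeric values, one per target id.
#' @export
worked_example_targets <- function() {
  out <- list()

  gene_body_pct <- function(n_features, n_hit) {
    feats <- lattice_regions(n_features, width = 5000L, spacing = 20000L)
    ann <- GenomicRanges::GRanges(
      feats$chrom, IRanges::IRanges(feats$start + 1L, feats$end),
      category = "gene_body",
      gene = sprintf("G%05d", seq_len(n_features)),
      name = sprintf("gene_body:G%05d", seq_len(n_features)))
    dmrs <- lattice_regions(n_hit, width = 600L, spacing = 20000L,
                            offset = 1000L)
    enr <- features_containing_dmrs(ann, dmrs)$enrichment
    100 * enr$fraction[enr$category == "gene_body"]
  }
  out$t1 <- gene_body_pct(18951L, 1426L)
  out$t2 <- gene_body_pct(22026L, 1375L)

  # overlap of the non-R882 and R882 human DMR sets: 215 shared pairs
  r882 <- lattice_regions(2209L)
  non_r882 <- rbind(
    within(lattice_regions(215L), start <- start + 100L),
    lattice_regions(117L, offset = 2209L * 50000L + 1000000L))
  non_r882$end <- non_r882$start + 600L
  out$t3 <- compare_dmr_sets(non_r882, r882)$direct_pct
  out$t4 <- compare_dmr_sets(r882, non_r882)$direct_pct

  # cross-species correspondence: direct and within-10 kb counts per
  # direction, percent over the full source set
  correspondence <- function(n_src, n_direct, n_within) {
    src <- lattice_regions(n_src)
    tgt <- rbind(
      within(lattice_regions(n_direct), start <- start + 100L),
      within(lattice_regions(n_within - n_direct,
                             offset = n_direct * 50000L),
             start <- start + 600L + 5000L))
    tgt$end <- tgt$start + 600L
    cmp <- compare_dmr_sets(src, tgt, k = 10000)
    list(direct = cmp$direct_pct, within = cmp$within_k_pct)
  }
  h2m <- correspondence(2209L, 101L, 1713L)
  out$t5 <- h2m$direct
  out$t6 <- h2m$within
  m2h <- correspondence(2172L, 95L, 1889L)
  out$t7 <- m2h$direct
  out$t8 <- m2h$within

  out$t9 <- t_test_from_summary(662.7, 441.6, 2209, 614.5, 366.8, 332)$p

  # cross-species DEG concordance: 121 of 242 human DEG symbols matched
  human <- data.frame(gene = sprintf("GENE%03d", 1:242),
                      direction = "up", cluster = "c1")
  mouse <- data.frame(
    gene = sprintf("Gene%03d", 1:121),  # case differs, symbols match
    direction = "up", cluster = "k1")
  out$t10 <- cross_species_deg_concordance(human, mouse)$percent

  # DEG genes within 10 kb of a DMR: 38 of 242
  gi <- lattice_regions(242L, width = 5000L, spacing = 100000L)
  gi$gene <- human$gene
  dmrs38 <- within(lattice_regions(38L, width = 500L, spacing = 100000L),
                   start <- start + 5000L + 5000L)
  dmrs38$end <- dmrs38$start + 500L
  out$t11 <- link_degs_to_dmrs(human, gi, dmrs38, k = 10000)$n_linked

  out
}
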