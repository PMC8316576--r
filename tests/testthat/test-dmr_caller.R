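test_that("segment_candidates finds runs and applies the CpG-count rule", {
  # 12 consecutive CpGs spaced 50 bp, per-CpG difference -0.30
  co <- toy_cohort(k = 12, test_level = 0.5, ref_level = 0.8)
  cand <- segment_candidates(co$matrix, co$metadata, "test", "ref")
  expect_equal(nrow(cand), 1L)
  expect_equal(length(cand$site_idx[[1]]), 12L)
  expect_equal(cand$start, co$matrix$sites$start[1])
  expect_equal(cand$end, co$matrix$sites$end[12])

  # 9 CpGs: below the (inclusive) 10-CpG minimum
  co9 <- toy_cohort(k = 9)
  expect_equal(nrow(segment_candidates(co9$matrix, co9$metadata,
                                       "test", "ref")), 0L)
  # exactly 10 CpGs: kept (>=10 is inclusive)
  co10 <- toy_cohort(k = 10)
  expect_equal(nrow(segment_candidates(co10$matrix, co10$metadata,
                                       "test", "ref")), 1L)
})

test_that("a >300 bp inter-CpG gap splits runs", {
  # 12 CpGs with a 500 bp gap after the 6th: two 6-CpG runs, both dropped
  samples <- c("t1", "t2", "r1", "r2")
  vals <- cbind(t1 = rep(0.49, 12), t2 = rep(0.51, 12),
                r1 = rep(0.79, 12), r2 = rep(0.81, 12))
  starts <- c(1000 + 50 * 0:5, 1800 + 50 * 0:5)  # gap 1800-1250 = 550
  sites <- data.frame(chrom = "chr1", start = as.integer(starts),
                      end = as.integer(starts) + 1L)
  cov <- matrix(20L, 12, 4, dimnames = list(NULL, samples))
  mat <- meth_matrix(sites, vals, cov)
  md <- toy_metadata(samples, c("test", "test", "ref", "ref"))
  expect_equal(nrow(segment_candidates(mat, md, "test", "ref")), 0L)
})

test_that("exact MWU p equals full enumeration (groups <= 8)", {
  expect_equal(focalmeth:::mwu_p(c(0.1, 0.2, 0.3), c(0.6, 0.7, 0.8)), 0.1)
  set.seed(7)
  for (i in 1:25) {
    n1 <- sample(3:6, 1); n2 <- sample(3:8, 1)
    x <- runif(n1); y <- runif(n2)
    expect_equal(focalmeth:::mwu_p(x, y), mwu_enum(x, y), tolerance = 1e-12)
  }
})

test_that("BH q-values match the step-up definition on random p-vectors", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04, 0.05), "BH"),
               c(0.04, 0.04, 0.05, 0.05))
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(c(3, 10, 100, 1000), 1))
    expect_equal(p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-10)
  }
})

test_that("score_and_filter rejects null candidates and computes stats", {
  co <- toy_cohort(k = 12, test_level = 0.8, ref_level = 0.8)
  # identical group levels: no candidate at all (difference ~0)
  cand <- segment_candidates(co$matrix, co$metadata, "test", "ref")
  expect_equal(nrow(cand), 0L)

  co2 <- toy_cohort(k = 12, test_level = 0.45, ref_level = 0.85)
  cand2 <- segment_candidates(co2$matrix, co2$metadata, "test", "ref")
  d <- score_and_filter(cand2, co2$matrix, co2$metadata, "test", "ref")
  expect_equal(nrow(d$records), 1L)
  expect_equal(d$records$mean_diff, -0.4, tolerance = 1e-9)
  expect_equal(d$records$p, 2 / choose(8, 3))  # exact MWU at 3 vs 5, U = 0
  expect_equal(d$records$direction, "hypo")
  expect_true(d$records$q >= d$records$p)
})

# Builds a cohort of 10-CpG blocks (20 bp spacing) separated by the given
# candidate-edge gaps; an all-uncovered CpG sits inside each gap so the
# segmentation cannot bridge blocks and merge_adjacent has work to do.
block_cohort <- function(gaps) {
  test_lv <- c(0.48, 0.52, 0.50)
  ref_lv <- c(0.78, 0.82, 0.80, 0.79, 0.81)
  samples <- c(paste0("t", 1:3), paste0("r", 1:5))
  starts <- integer(0)
  missing <- integer(0)
  s <- 1000L
  for (b in seq_len(length(gaps) + 1L)) {
    starts <- c(starts, s + 20L * 0:9)
    if (b <= length(gaps)) {
      cand_end <- s + 181L
      missing <- c(missing, cand_end + gaps[b] %/% 2L)
      s <- cand_end + gaps[b]
    }
  }
  all_starts <- sort(c(starts, missing))
  vals <- sapply(c(test_lv, ref_lv), rep, length(all_starts))
  colnames(vals) <- samples
  cov <- matrix(20L, length(all_starts), 8,
                dimnames = list(NULL, samples))
  bad <- all_starts %in% missing
  vals[bad, ] <- NA_real_
  cov[bad, ] <- 0L
  mat <- meth_matrix(data.frame(chrom = "chr1", start = all_starts,
                                end = all_starts + 1L), vals, cov)
  md <- toy_metadata(samples, rep(c("test", "ref"), c(3, 5)))
  list(matrix = mat, metadata = md)
}

test_that("merge_adjacent merges below 50 bp transitively and recomputes", {
  # gaps 40, 40 (merged transitively) then 60 (kept separate)
  bc <- block_cohort(c(40L, 40L, 60L))
  cand <- segment_candidates(bc$matrix, bc$metadata, "test", "ref")
  expect_equal(nrow(cand), 4L)
  scored <- score_and_filter(cand, bc$matrix, bc$metadata, "test", "ref")
  merged <- merge_adjacent(scored, bc$matrix, bc$metadata)
  expect_equal(nrow(merged$records), 2L)
  expect_equal(merged$records$n_cpgs[1], 30L)  # union of member CpGs
  expect_equal(merged$records$start[1], 1000L)
  expect_equal(merged$records$n_cpgs[2], 10L)
  # merged statistics recomputed over the union
  expect_equal(merged$records$mean_diff[1], -0.3, tolerance = 1e-9)
  # idempotent
  again <- merge_adjacent(merged, bc$matrix, bc$metadata)
  expect_equal(again$records$start, merged$records$start)
  expect_equal(again$records$end, merged$records$end)
  # total CpG count conserved; widths >= widest member
  expect_equal(sum(again$records$n_cpgs), sum(scored$records$n_cpgs))
  expect_gte(min(merged$records$width_bp), 181L)  # widest member width
})

test_that("merge boundary: gap 40 merges, gap 60 does not", {
  n_after <- function(gap) {
    bc <- block_cohort(gap)
    scored <- score_and_filter(
      segment_candidates(bc$matrix, bc$metadata, "test", "ref"),
      bc$matrix, bc$metadata, "test", "ref")
    nrow(merge_adjacent(scored, bc$matrix, bc$metadata)$records)
  }
  expect_equal(n_after(40L), 1L)
  expect_equal(n_after(60L), 2L)
})

test_that("canonicality filter: SD <= 0.1 in both groups, inclusive", {
  refm <- c(0.80, 0.81, 0.79, 0.82, 0.78)
  mkset <- function(test_means, ref_means = refm) {
    k <- 12
    samples <- c(paste0("t", seq_along(test_means)),
                 paste0("r", seq_along(ref_means)))
    vals <- sapply(c(test_means, ref_means), rep, k)
    colnames(vals) <- samples
    mat <- toy_matrix(vals)
    md <- toy_metadata(samples, rep(c("test", "ref"),
                                    c(length(test_means),
                                      length(ref_means))))
    scored <- score_and_filter(
      segment_candidates(mat, md, "test", "ref"), mat, md, "test", "ref")
    suppressMessages(canonicality_filter(scored))
  }
  kept <- mkset(c(0.30, 0.32, 0.31))
  expect_equal(nrow(kept$records), 1L)
  removed <- mkset(c(0.10, 0.40, 0.70))
  expect_equal(nrow(removed$records), 0L)
  # boundary: within-group SD exactly 0.1 is kept (inclusive)
  tm <- c(0.30, 0.40, 0.50)
  expect_equal(sd(tm), 0.1)
  boundary <- mkset(tm)
  expect_equal(nrow(boundary$records), 1L)
})

test_that("filters only remove records, never modify coordinates", {
  set.seed(3)
  cfg <- sim_config(seed = 3, n_chroms = 1L, chrom_length = 5e5,
                    n_regions = 8L, ko_extra_regions = 4L,
                    noisy_region_fraction = 0.3)
  g <- simulate_genome_cpgs(cfg)
  sim <- simulate_methylation_samples(cfg, g, tier = "severe")
  cand <- segment_candidates(sim$matrix, sim$metadata, "test", "ref")
  scored <- score_and_filter(cand, sim$matrix, sim$metadata, "test", "ref")
  filt <- suppressMessages(canonicality_filter(scored))
  key_in <- paste(scored$records$chrom, scored$records$start,
                  scored$records$end)
  key_out <- paste(filt$records$chrom, filt$records$start,
                   filt$records$end)
  expect_true(all(key_out %in% key_in))
  expect_lte(nrow(filt$records), nrow(scored$records))
})

test_that("covariate regression recovers a planted genotype effect", {
  set.seed(21)
  n_test <- 6; n_ref <- 10
  samples <- c(paste0("t", 1:n_test), paste0("r", 1:n_ref))
  md <- toy_metadata(samples, rep(c("test", "ref"), c(n_test, n_ref)),
                     ages = exp(runif(16, log(2), log(43))))
  genotype <- as.integer(md$group == "test")
  # regional means = 0.8 - 0.3*genotype + noise(SD 0.02), 5 regions
  sm <- t(replicate(5, 0.8 - 0.3 * genotype + rnorm(16, 0, 0.02)))
  colnames(sm) <- samples
  dmrs <- structure(list(
    records = data.frame(id = paste0("dmr_", 1:5), chrom = "chr1",
                         start = 1:5 * 1000L, end = 1:5 * 1000L + 500L),
    sample_means = sm,
    groups = list(test = "test", ref = "ref"),
    samples = list(test = samples[1:6], ref = samples[7:16])),
    class = "dmr_set")
  res <- covariate_regression(dmrs, md)
  expect_true(all(res$genotype_coef > -0.33 & res$genotype_coef < -0.27))
  expect_true(all(res$genotype_q < 0.05))
  expect_false(any(res$singular))

  # genotype identical across samples: singular design flagged
  md2 <- md; md2$group <- "test"
  dmrs2 <- dmrs; dmrs2$samples <- list(test = samples, ref = character(0))
  res2 <- covariate_regression(dmrs2, md2)
  expect_true(all(res2$singular))
})

test_that("age-only effects are not attributed to genotype", {
  set.seed(31)
  hits <- 0L
  for (s in 1:20) {
    md <- toy_metadata(c(paste0("t", 1:6), paste0("r", 1:10)),
                       rep(c("test", "ref"), c(6, 10)),
                       ages = exp(runif(16, log(2), log(43))))
    sm <- matrix(0.8 - 0.05 * log(md$age) + rnorm(16, 0, 0.02), 1,
                 dimnames = list(NULL, md$sample))
    dmrs <- structure(list(
      records = data.frame(id = "dmr_1", chrom = "chr1", start = 0L,
                           end = 100L),
      sample_means = sm, groups = list(test = "test", ref = "ref"),
      samples = list(test = md$sample[1:6], ref = md$sample[7:16])),
      class = "dmr_set")
    res <- covariate_regression(dmrs, md)
    if (!is.na(res$genotype_q) && res$genotype_q < 0.05) hits <- hits + 1L
  }
  expect_lte(hits, 2L)  # >= 18/20 null seeds stay non-significant
})

test_that("dmr_summary width t-test and 1 bp overlap counts", {
  ts <- t_test_from_summary(662.7, 441.6, 2209, 614.5, 366.8, 332)
  expect_equal(ts$p, 0.0587, tolerance = 0.002 / 0.0587)
  # identical summary stats: t = 0, p = 1
  ts0 <- t_test_from_summary(5, 1, 10, 5, 1, 10)
  expect_equal(ts0$t, 0)
  expect_equal(ts0$p, 1)

  a <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  b1 <- data.frame(chrom = "chr1", start = 199L, end = 300L)
  b2 <- data.frame(chrom = "chr1", start = 200L, end = 300L)
  expect_equal(dmr_summary(a, b1)$overlap$a_with_b, 1L)
  expect_equal(dmr_summary(a, b2)$overlap$a_with_b, 0L)
})

test_that("replicate correlation: identity, anti-correlation, QC flag", {
  set.seed(5)
  v <- runif(200)
  vals <- cbind(a = v, b = v, c = 1 - v)
  mat <- toy_matrix(vals)
  md <- toy_metadata(c("a", "b", "c"), c("g1", "g1", "g2"))
  rc <- replicate_correlation(mat, md)
  expect_equal(rc$correlations$g1["a", "b"], 1)
  expect_true(rc$qc_pass)
  md2 <- toy_metadata(c("a", "b", "c"), c("g1", "g1", "g1"))
  rc2 <- replicate_correlation(mat, md2)
  expect_false(rc2$qc_pass)
  expect_equal(min(rc2$correlations$g1, na.rm = TRUE), -1)
})

test_that("mild-tier DMRs nest inside severe-tier DMRs on shared truth", {
  shared <- 0L; nested <- 0L
  for (s in c(2, 9)) {
    cfg <- sim_config(seed = s, n_chroms = 2L, chrom_length = 1e6,
                      n_regions = 50L, ko_extra_regions = 0L,
                      n_age_regions = 2L)
    g <- simulate_genome_cpgs(cfg)
    call_tier <- function(tier) {
      sim <- simulate_methylation_samples(cfg, g, tier = tier)
      suppressWarnings(call_dmrs(sim$matrix, sim$metadata, "test",
                                 "ref"))$records
    }
    sev <- call_tier("severe")
    mild <- call_tier("mild")
    if (!nrow(mild)) next
    shared <- shared + nrow(mild)
    nested <- nested +
      overlap_brute(mild[, c("chrom", "start", "end")],
                    sev[, c("chrom", "start", "end")])$n_with_hit
  }
  expect_gt(shared, 0L)
  expect_gte(nested / shared, 0.9)
})
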