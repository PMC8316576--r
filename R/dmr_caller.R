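# ---------------------------------------------------------------------------
# DMR calling: seed-and-extend segmentation over per-CpG group-mean
# differences, exact Mann-Whitney region test, BH FDR, <50 bp merging, and
# the canonicality (within-group SD) filter.
# ---------------------------------------------------------------------------

#' DMR calling parameters
#'
#' Thresholds follow the published focal-hypomethylation criteria: a DMR
#' spans at least \code{min_cpgs} CpGs (inclusive), has an absolute
#' between-group mean methylation difference of at least
#' \code{min_mean_diff}, a Benjamini-Hochberg FDR of at most \code{max_fdr},
#' and a within-group standard deviation of per-sample regional means of at
#' most \code{max_within_group_sd}; adjacent DMRs closer than
#' \code{merge_gap_bp} are merged.
#'
#' @param min_cpgs minimum CpGs per region (default 10, inclusive).
#' @param min_mean_diff minimum |group mean difference| (default 0.2).
#' @param max_fdr BH FDR ceiling (default 0.05).
#' @param max_within_group_sd canonicality SD ceiling (default 0.1,
#'   inclusive), applied to both groups unless \code{sd_both_groups} is
#'   FALSE (then test group only).
#' @param merge_gap_bp merge regions with gap strictly below this (50).
#' @param max_intersite_gap_bp maximum distance between consecutive CpGs in
#'   a candidate run (300, the conventional segmentation neighborhood).
#' @param min_samples_per_group_at_cpg minimum covered samples per group for
#'   a CpG to enter a run (2).
#' @param sd_both_groups apply the SD filter to both groups (TRUE).
#' @param coverage_weighted use coverage-weighted regional means (FALSE;
#'   default is the unweighted mean of covered CpG ratios).
#' @return A list of class \code{dmr_params}.
#' @export
dmr_params <- function(min_cpgs = 10L, min_mean_diff = 0.2, max_fdr = 0.05,
                       max_within_group_sd = 0.1, merge_gap_bp = 50L,
                       max_intersite_gap_bp = 300L,
                       min_samples_per_group_at_cpg = 2L,
                       sd_both_groups = TRUE, coverage_weighted = FALSE) {
  p <- list(min_cpgs = as.integer(min_cpgs),
            min_mean_diff = min_mean_diff, max_fdr = max_fdr,
            max_within_group_sd = max_within_group_sd,
            merge_gap_bp = as.integer(merge_gap_bp),
            max_intersite_gap_bp = as.integer(max_intersite_gap_bp),
            min_samples_per_group_at_cpg =
              as.integer(min_samples_per_group_at_cpg),
            sd_both_groups = isTRUE(sd_both_groups),
            coverage_weighted = isTRUE(coverage_weighted))
  stopifnot(p$min_cpgs > 0, p$min_mean_diff > 0, p$min_mean_diff <= 1,
            p$max_fdr > 0, p$max_within_group_sd > 0, p$merge_gap_bp > 0,
            p$max_intersite_gap_bp > 0, p$min_samples_per_group_at_cpg > 0)
  class(p) <- "dmr_params"
  p
}

group_samples <- function(metadata, group, samples) {
  s <- metadata$sample[metadata$group == group]
  s <- intersect(s, samples)
  if (!length(s)) stop("group '", group, "' absent from metadata/matrix")
  s
}

# Exact two-sided Mann-Whitney U p-value. Exact enumeration (via the exact
# null distribution) when both groups have <= 8 observations and no ties;
# otherwise mid-rank normal approximation with continuity correction.
mwu_p <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) return(NA_real_)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 8 && length(y) <= 8
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value)
}

# Per-sample regional means over a set of CpG row indices.
regional_means <- function(mat, idx, coverage_weighted = FALSE) {
  r <- mat$ratio[idx, , drop = FALSE]
  if (coverage_weighted) {
    w <- mat$coverage[idx, , drop = FALSE]
    out <- colSums(r * w, na.rm = TRUE) / colSums(w * !is.na(r))
    out[colSums(w * !is.na(r)) == 0] <- NA_real_
    out
  } else {
    colMeans(r, na.rm = TRUE)
  }
}

#' Segment candidate differentially methylated runs
#'
#' Seed-and-extend scan over CpGs in coordinate order. A candidate is a
#' maximal run of consecutive CpGs in which (a) each CpG is covered in at
#' least \code{min_samples_per_group_at_cpg} samples of each group, (b)
#' consecutive CpGs are at most \code{max_intersite_gap_bp} apart, (c) the
#' per-CpG group-mean difference (test minus reference) keeps one sign and
#' the running mean of the absolute difference stays at or above
#' \code{min_mean_diff}, and (d) the run holds at least \code{min_cpgs}
#' CpGs. The scan is greedy left-to-right and fully deterministic.
#'
#' @param mat a \code{\link{meth_matrix}}.
#' @param metadata sample metadata data.frame.
#' @param test_group,ref_group group labels.
#' @param params a \code{\link{dmr_params}}.
#' @return data.frame of candidates with a \code{site_idx} list-column of
#'   CpG row indices.
#' @export
segment_candidates <- function(mat, metadata, test_group, ref_group,
                               params = dmr_params()) {
  validate_metadata(metadata)
  ts <- group_samples(metadata, test_group, mat$samples)
  rs <- group_samples(metadata, ref_group, mat$samples)
  n <- nrow(mat$sites)
  out <- list()
  if (n == 0L) return(empty_candidates())
  cov_t <- rowSums(mat$coverage[, ts, drop = FALSE] > 0)
  cov_r <- rowSums(mat$coverage[, rs, drop = FALSE] > 0)
  m_t <- rowMeans(mat$ratio[, ts, drop = FALSE], na.rm = TRUE)
  m_r <- rowMeans(mat$ratio[, rs, drop = FALSE], na.rm = TRUE)
  d <- m_t - m_r
  eligible <- cov_t >= params$min_samples_per_group_at_cpg &
    cov_r >= params$min_samples_per_group_at_cpg & !is.na(d)
  chrom <- mat$sites$chrom
  pos <- mat$sites$start
  run <- integer(0)
  run_sum <- 0
  run_sign <- 0
  close_run <- function() {
    if (length(run) >= params$min_cpgs) {
      out[[length(out) + 1L]] <<- list(
        chrom = chrom[run[1]], start = pos[run[1]],
        end = mat$sites$end[run[length(run)]], site_idx = run)
    }
    run <<- integer(0); run_sum <<- 0; run_sign <<- 0
  }
  for (i in seq_len(n)) {
    if (!eligible[i]) { close_run(); next }
    di <- d[i]
    if (length(run)) {
      same_chrom <- chrom[i] == chrom[run[length(run)]]
      gap_ok <- same_chrom &&
        (pos[i] - pos[run[length(run)]]) <= params$max_intersite_gap_bp
      sign_ok <- sign(di) == run_sign && di != 0
      mean_ok <- abs(run_sum + di) / (length(run) + 1) >= params$min_mean_diff
      if (gap_ok && sign_ok && mean_ok) {
        run <- c(run, i); run_sum <- run_sum + di
        next
      }
      close_run()
    }
    if (abs(di) >= params$min_mean_diff && di != 0) {
      run <- i; run_sum <- di; run_sign <- sign(di)
    }
  }
  close_run()
  if (!length(out)) return(empty_candidates())
  cand <- data.frame(chrom = vapply(out, `[[`, "", "chrom"),
                     start = vapply(out, `[[`, 0L, "start"),
                     end = vapply(out, `[[`, 0L, "end"))
  cand$site_idx <- lapply(out, `[[`, "site_idx")
  cand
}

empty_candidates <- function() {
  cand <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0))
  cand$site_idx <- list()
  cand
}

new_dmr_set <- function(records, sample_means, site_idx, test_group,
                        ref_group, test_samples, ref_samples) {
  structure(list(records = records, sample_means = sample_means,
                 site_idx = site_idx,
                 groups = list(test = test_group, ref = ref_group),
                 samples = list(test = test_samples, ref = ref_samples)),
            class = "dmr_set")
}

#' @export
print.dmr_set <- function(x, ...) {
  cat(sprintf("dmr_set: %d region(s), %s vs %s\n", nrow(x$records),
              x$groups$test, x$groups$ref))
  invisible(x)
}

#' @export
as.data.frame.dmr_set <- function(x, ...) {
  df <- x$records
  if (nrow(df) && !is.null(x$sample_means)) {
    sm <- as.data.frame(x$sample_means)
    names(sm) <- paste0("mean.", colnames(x$sample_means))
    df <- cbind(df, sm)
  }
  rownames(df) <- NULL
  df
}

score_candidates <- function(cand, mat, metadata, test_group, ref_group,
                             params) {
  ts <- group_samples(metadata, test_group, mat$samples)
  rs <- group_samples(metadata, ref_group, mat$samples)
  k <- nrow(cand)
  sm <- matrix(NA_real_, k, length(mat$samples),
               dimnames = list(NULL, mat$samples))
  keep <- rep(TRUE, k)
  nas <- rep(NA_real_, k)
  rec <- data.frame(chrom = cand$chrom, start = cand$start, end = cand$end,
                    n_cpgs = vapply(cand$site_idx, length, 0L),
                    mean_test = nas, mean_ref = nas,
                    mean_diff = nas, sd_test = nas,
                    sd_ref = nas, p = nas, q = nas,
                    stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    m <- regional_means(mat, cand$site_idx[[i]], params$coverage_weighted)
    sm[i, ] <- m
    tv <- m[ts][!is.na(m[ts])]
    rv <- m[rs][!is.na(m[rs])]
    if (!length(tv) || !length(rv)) {
      warning("candidate ", i, " lost all samples of a group; dropped")
      keep[i] <- FALSE
      next
    }
    rec$mean_test[i] <- mean(tv)
    rec$mean_ref[i] <- mean(rv)
    rec$mean_diff[i] <- mean(tv) - mean(rv)
    rec$sd_test[i] <- if (length(tv) >= 2) sd(tv) else NA_real_
    rec$sd_ref[i] <- if (length(rv) >= 2) sd(rv) else NA_real_
    rec$p[i] <- mwu_p(m[ts], m[rs])
  }
  rec <- rec[keep, , drop = FALSE]
  sm <- sm[keep, , drop = FALSE]
  list(rec = rec, sm = sm, site_idx = cand$site_idx[keep])
}

finalize_records <- function(rec) {
  rec$q <- p.adjust(rec$p, method = "BH")
  rec$width_bp <- rec$end - rec$start
  rec$direction <- ifelse(rec$mean_diff < 0, "hypo", "hyper")
  rec
}

#' Score candidates and apply the FDR and mean-difference filters
#'
#' Each candidate gets per-sample regional means (unweighted over covered
#' CpGs), group means and SDs, a two-sided exact Mann-Whitney U p-value on
#' the per-sample regional means, and a BH q-value computed across all
#' candidates genome-wide. Candidates with q at most \code{max_fdr} and
#' |mean difference| at least \code{min_mean_diff} survive.
#'
#' @inheritParams segment_candidates
#' @param cand output of \code{\link{segment_candidates}}.
#' @return A \code{dmr_set} of provisional records.
#' @export
score_and_filter <- function(cand, mat, metadata, test_group, ref_group,
                             params = dmr_params()) {
  ts <- group_samples(metadata, test_group, mat$samples)
  rs <- group_samples(metadata, ref_group, mat$samples)
  sc <- score_candidates(cand, mat, metadata, test_group, ref_group, params)
  rec <- finalize_records(sc$rec)
  keep <- !is.na(rec$q) & rec$q <= params$max_fdr &
    abs(rec$mean_diff) >= params$min_mean_diff
  new_dmr_set(rec[keep, , drop = FALSE], sc$sm[keep, , drop = FALSE],
              sc$site_idx[keep], test_group, ref_group, ts, rs)
}

#' Merge DMRs separated by less than the merge gap
#'
#' Same-chromosome records whose gap (next start minus previous end) is
#' strictly below \code{merge_gap_bp} are merged transitively. Statistics of
#' merged records are recomputed over the union of member CpGs and q-values
#' are re-assigned by BH over the post-merge set (merged regions are new
#' hypotheses).
#'
#' @param dmrs a \code{dmr_set}.
#' @param mat the \code{\link{meth_matrix}} used to call the records.
#' @param metadata sample metadata.
#' @param params a \code{\link{dmr_params}}.
#' @return A merged \code{dmr_set}.
#' @export
merge_adjacent <- function(dmrs, mat, metadata, params = dmr_params()) {
  rec <- dmrs$records
  if (nrow(rec) <= 1) {
    dmrs$records <- finalize_records(rec)
    return(dmrs)
  }
  o <- order(rec$chrom, rec$start)
  rec <- rec[o, , drop = FALSE]
  idx <- dmrs$site_idx[o]
  grp <- integer(nrow(rec))
  g <- 1L
  grp[1] <- g
  for (i in 2:nrow(rec)) {
    gap <- rec$start[i] - max(rec$end[grp == g & seq_len(nrow(rec)) < i])
    if (rec$chrom[i] == rec$chrom[i - 1] && gap < params$merge_gap_bp) {
      grp[i] <- g
    } else {
      g <- g + 1L
      grp[i] <- g
    }
  }
  merged_idx <- lapply(split(seq_len(nrow(rec)), grp), function(members) {
    sort(unique(unlist(idx[members])))
  })
  cand <- data.frame(
    chrom = vapply(split(rec$chrom, grp), `[`, "", 1),
    start = vapply(split(rec$start, grp), min, 0),
    end = vapply(split(rec$end, grp), max, 0))
  cand$site_idx <- merged_idx
  sc <- score_candidates(cand, mat, metadata, dmrs$groups$test,
                         dmrs$groups$ref, params)
  new_dmr_set(finalize_records(sc$rec), sc$sm, sc$site_idx,
              dmrs$groups$test, dmrs$groups$ref,
              dmrs$samples$test, dmrs$samples$ref)
}

#' Remove non-canonical DMRs
#'
#' A canonical DMR has reproducible per-sample regional means: the SD within
#' each group must be at most \code{max_within_group_sd} (inclusive). With
#' \code{sd_both_groups = FALSE} only the test group is checked. Records in
#' groups of fewer than two samples have undefined SD and are kept with a
#' warning flag (\code{sd_flag} column).
#'
#' @param dmrs a \code{dmr_set}.
#' @param params a \code{\link{dmr_params}}.
#' @return Filtered \code{dmr_set}; the number removed is reported via
#'   \code{message}.
#' @export
canonicality_filter <- function(dmrs, params = dmr_params()) {
  rec <- dmrs$records
  if (!nrow(rec)) return(dmrs)
  flag <- is.na(rec$sd_test) | (params$sd_both_groups & is.na(rec$sd_ref))
  ok_t <- is.na(rec$sd_test) | rec$sd_test <= params$max_within_group_sd
  ok_r <- if (params$sd_both_groups)
    is.na(rec$sd_ref) | rec$sd_ref <= params$max_within_group_sd
  else rep(TRUE, nrow(rec))
  keep <- ok_t & ok_r
  if (any(flag[keep]))
    warning(sum(flag[keep]), " record(s) kept with undefined within-group SD")
  message(sum(!keep), " non-canonical DMR(s) removed (within-group SD > ",
          params$max_within_group_sd, ")")
  rec$sd_flag <- flag
  dmrs$records <- rec[keep, , drop = FALSE]
  dmrs$sample_means <- dmrs$sample_means[keep, , drop = FALSE]
  dmrs$site_idx <- dmrs$site_idx[keep]
  dmrs
}

#' Call differentially methylated regions
#'
#' Full pipeline: \code{\link{segment_candidates}} then
#' \code{\link{score_and_filter}} then \code{\link{merge_adjacent}} then
#' \code{\link{canonicality_filter}}. Deterministic given its inputs.
#' Records carry stable ids \code{dmr_1..dmr_n} in coordinate order, and the
#' filter-cascade counts are attached as the \code{cascade} attribute.
#'
#' @inheritParams segment_candidates
#' @return A \code{dmr_set}.
#' @export
call_dmrs <- function(mat, metadata, test_group, ref_group,
                      params = dmr_params()) {
  cand <- segment_candidates(mat, metadata, test_group, ref_group, params)
  scored <- score_and_filter(cand, mat, metadata, test_group, ref_group,
                             params)
  merged <- merge_adjacent(scored, mat, metadata, params)
  final <- suppressMessages(canonicality_filter(merged, params))
  o <- order(final$records$chrom, final$records$start)
  final$records <- final$records[o, , drop = FALSE]
  final$sample_means <- final$sample_means[o, , drop = FALSE]
  final$site_idx <- final$site_idx[o]
  final$records$id <- if (nrow(final$records))
    paste0("dmr_", seq_len(nrow(final$records))) else character(0)
  final$records <- final$records[, c("id", setdiff(names(final$records),
                                                   "id"))]
  rownames(final$records) <- NULL
  attr(final, "cascade") <- c(candidates = nrow(cand),
                              post_fdr = nrow(scored$records),
                              post_merge = nrow(merged$records),
                              post_sd = nrow(final$records))
  attr(final, "params") <- params
  final
}

#' Covariate sensitivity regression for called DMRs
#'
#' Per DMR, ordinary least squares of the per-sample regional mean on a
#' genotype indicator (test group = 1), a sex indicator, and log(age); the
#' genotype coefficient is tested two-sided (t-test) and BH-adjusted across
#' DMRs. Singular designs (e.g. sex confounded with genotype) are flagged
#' and their coefficient reported as NA.
#'
#' @param dmrs a \code{dmr_set} from \code{\link{call_dmrs}}.
#' @param metadata sample metadata with \code{age} and \code{sex}.
#' @return data.frame: id, genotype_coef, genotype_p, genotype_q,
#'   significant (q < 0.05), singular flag.
#' @export
covariate_regression <- function(dmrs, metadata) {
  validate_metadata(metadata)
  samp <- c(dmrs$samples$test, dmrs$samples$ref)
  md <- metadata[match(samp, metadata$sample), ]
  genotype <- as.integer(md$group == dmrs$groups$test)
  sexm <- as.integer(md$sex == "M")
  lage <- log(md$age)
  n <- nrow(dmrs$records)
  out <- data.frame(id = dmrs$records$id, genotype_coef = NA_real_,
                    genotype_p = NA_real_, genotype_q = NA_real_,
                    singular = FALSE, stringsAsFactors = FALSE)
  if (length(unique(genotype)) < 2) {
    out$singular <- TRUE
    return(out)
  }
  for (i in seq_len(n)) {
    y <- dmrs$sample_means[i, samp]
    fit <- lm(y ~ genotype + sexm + lage)
    cf <- summary(fit)$coefficients
    if (anyNA(coef(fit)) || !"genotype" %in% rownames(cf)) {
      out$singular[i] <- TRUE
      next
    }
    out$genotype_coef[i] <- cf["genotype", "Estimate"]
    out$genotype_p[i] <- cf["genotype", "Pr(>|t|)"]
  }
  out$genotype_q <- p.adjust(out$genotype_p, method = "BH")
  out$significant <- !is.na(out$genotype_q) & out$genotype_q < 0.05
  out
}

#' Two-sample pooled-variance t-test from summary statistics
#'
#' @param m1,s1,n1 mean, SD, and size of the first sample.
#' @param m2,s2,n2 mean, SD, and size of the second sample.
#' @return list with \code{t}, \code{df}, \code{p} (two-tailed).
#' @export
t_test_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Summarize one or two DMR sets
#'
#' Per set: count, width mean and SD, mean regional methylation per group.
#' With two sets, a two-tailed pooled-variance two-sample t-test compares
#' widths, and 1 bp-overlap intersection counts are reported for both
#' scanning directions.
#'
#' @param dmrsA a \code{dmr_set} or region data.frame.
#' @param dmrsB optional second set.
#' @return list with \code{summary} (data.frame) and, with two sets,
#'   \code{width_ttest} and \code{overlap}.
#' @export
dmr_summary <- function(dmrsA, dmrsB = NULL) {
  one <- function(x, label) {
    df <- as.data.frame(x)
    if (!nrow(df))
      return(data.frame(set = label, n = 0L, width_mean = NA_real_,
                        width_sd = NA_real_, mean_test = NA_real_,
                        mean_ref = NA_real_))
    w <- df$end - df$start
    data.frame(set = label, n = nrow(df), width_mean = mean(w),
               width_sd = sd(w),
               mean_test = if ("mean_test" %in% names(df))
                 mean(df$mean_test) else NA_real_,
               mean_ref = if ("mean_ref" %in% names(df))
                 mean(df$mean_ref) else NA_real_)
  }
  res <- list(summary = one(dmrsA, "A"))
  if (!is.null(dmrsB)) {
    res$summary <- rbind(res$summary, one(dmrsB, "B"))
    sa <- res$summary[1, ]
    sb <- res$summary[2, ]
    if (sa$n >= 2 && sb$n >= 2)
      res$width_ttest <- t_test_from_summary(sa$width_mean, sa$width_sd,
                                             sa$n, sb$width_mean,
                                             sb$width_sd, sb$n)
    al <- align_seqlevels(df_to_gr(as.data.frame(dmrsA)),
                          df_to_gr(as.data.frame(dmrsB)))
    hits <- GenomicRanges::findOverlaps(al[[1]], al[[2]], minoverlap = 1L)
    res$overlap <- list(
      a_with_b = length(unique(S4Vectors::queryHits(hits))),
      b_with_a = length(unique(S4Vectors::subjectHits(hits))),
      pairs = length(hits))
  }
  res
}

#' Within-group pairwise replicate correlations
#'
#' Pearson r over CpGs covered in both members of each within-group pair.
#' A QC flag is raised when any within-group pair has r <= 0.8, the
#' conventional reproducibility bar for WGBS replicates.
#'
#' @param mat a \code{\link{meth_matrix}}.
#' @param metadata sample metadata.
#' @return list with per-group correlation matrices, \code{qc_pass}, and a
#'   table of flagged pairs.
#' @export
replicate_correlation <- function(mat, metadata, min_r = 0.8) {
  validate_metadata(metadata)
  groups <- unique(metadata$group)
  out <- list()
  flagged <- data.frame(group = character(0), s1 = character(0),
                        s2 = character(0), r = numeric(0))
  for (g in groups) {
    s <- intersect(metadata$sample[metadata$group == g], mat$samples)
    if (length(s) < 2) next
    cm <- matrix(NA_real_, length(s), length(s), dimnames = list(s, s))
    diag(cm) <- 1
    for (i in seq_along(s)) for (j in seq_len(i - 1L)) {
      ok <- !is.na(mat$ratio[, s[i]]) & !is.na(mat$ratio[, s[j]])
      r <- if (sum(ok) >= 2)
        cor(mat$ratio[ok, s[i]], mat$ratio[ok, s[j]]) else NA_real_
      cm[i, j] <- cm[j, i] <- r
      if (is.na(r) || r <= min_r)
        flagged <- rbind(flagged,
                         data.frame(group = g, s1 = s[i], s2 = s[j], r = r))
    }
    out[[g]] <- cm
  }
  list(correlations = out, qc_pass = nrow(flagged) == 0, flagged = flagged)
}
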