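# Independent brute-force oracles used across the suite. These deliberately
# re-derive each statistic from its definition and never call the package's
# own code paths.

# BH q-values straight from the definition: q_i is the smallest n*t/#{p<=t}
# over candidate thresholds t >= p_i, capped at 1.
bh_brute <- function(p) {
  n <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi - 1e-15]
    min(1, min(vapply(ts, function(t) n * t / sum(p <= t + 1e-15), 0)))
  }, 0)
}

# Exact two-sided Mann-Whitney p by full enumeration of label assignments.
mwu_enum <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  centre <- n1 * length(y) / 2
  idx <- combn(length(pooled), n1)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9)
}

# Two-sided Fisher exact p by hypergeometric enumeration with fixed margins.
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  a_rng <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- dhyper(a_rng, c1, N - c1, r1)
  p_obs <- dhyper(tab[1, 1], c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson chi-squared statistic from the textbook formula, no correction.
chisq_manual <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Quadratic brute-force overlap and nearest-distance on 0-based half-open
# interval data.frames (chrom, start, end).
overlap_brute <- function(a, b) {
  hits <- 0L
  pairs <- 0L
  for (i in seq_len(nrow(a))) {
    any_hit <- FALSE
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] && a$start[i] < b$end[j] &&
          b$start[j] < a$end[i]) {
        any_hit <- TRUE
        pairs <- pairs + 1L
      }
    }
    hits <- hits + any_hit
  }
  list(n_with_hit = hits, pairs = pairs)
}

nearest_brute <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    ds <- Inf
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      d <- max(0, max(a$start[i], b$start[j]) - min(a$end[i], b$end[j]))
      ds <- min(ds, d)
    }
    ds
  }, 0)
}

# Toy methylation matrix builder: one chromosome, evenly spaced CpGs, with
# per-sample ratio vectors supplied column-wise (NA = uncovered).
toy_matrix <- function(ratios, spacing = 50, coverage = 20L,
                       chrom = "chr1", start0 = 1000L) {
  ratios <- as.matrix(ratios)
  n <- nrow(ratios)
  sites <- data.frame(chrom = chrom,
                      start = start0 + spacing * (seq_len(n) - 1L),
                      end = start0 + spacing * (seq_len(n) - 1L) + 1L)
  cov <- matrix(coverage, n, ncol(ratios),
                dimnames = list(NULL, colnames(ratios)))
  cov[is.na(ratios)] <- 0L
  meth_matrix(sites, ratios, cov)
}

toy_metadata <- function(samples, groups, ages = NULL, sexes = NULL) {
  n <- length(samples)
  data.frame(sample = samples, group = groups,
             age = if (is.null(ages)) rep(10, n) else ages,
             sex = if (is.null(sexes)) rep_len(c("M", "F"), n) else sexes,
             stringsAsFactors = FALSE)
}

# Two-group toy cohort: k CpGs at the given per-group mean levels plus
# deterministic per-sample offsets (keeps within-group SDs tiny). 3 vs 5
# by default so the exact MWU minimum (2/56 ~ 0.036) can clear FDR 0.05.
toy_cohort <- function(k = 12, test_level = 0.5, ref_level = 0.8,
                       n_test = 3, n_ref = 5, spacing = 50,
                       offsets_test = NULL, offsets_ref = NULL) {
  if (is.null(offsets_test))
    offsets_test <- seq(-0.01, 0.01, length.out = n_test)
  if (is.null(offsets_ref))
    offsets_ref <- seq(-0.01, 0.01, length.out = n_ref)
  samples <- c(paste0("t", seq_len(n_test)), paste0("r", seq_len(n_ref)))
  m <- sapply(c(test_level + offsets_test, ref_level + offsets_ref),
              function(lv) rep(lv, k))
  colnames(m) <- samples
  list(matrix = toy_matrix(m, spacing = spacing),
       metadata = toy_metadata(samples,
                               rep(c("test", "ref"), c(n_test, n_ref))))
}
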