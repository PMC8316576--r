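# ---------------------------------------------------------------------------
# Seeded synthetic data with the statistical structure of two-group WGBS
# cohorts (beta-binomial CpG counts at ~18x), chain-linked genome pairs,
# and clustered scRNA count matrices with planted DEGs. Ground truth is
# returned alongside the data and is never consumed by the pipeline.
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Defaults state the emulated world: ~18x negative-binomial coverage, CpG
#' islands (hypomethylated, dense) on a hypermethylated background, planted
#' focal hypomethylated regions with a lognormal width distribution around
#' a ~650 bp median, per-tier effect depths (severe -0.35, mild -0.12,
#' haploinsufficient -0.03, knockout -0.55 with extra regions), 60 percent
#' of planted regions inside gene bodies, mouse-like 6 vs 10 cohorts with
#' log-uniform ages 2-43 and balanced sexes, and per-sample beta jitter
#' with concentration 200 (regional SD ~0.03) plus a 5 percent noisy-region
#' fraction (concentration 12, SD ~0.2) to exercise the canonicality
#' filter.
#'
#' @param seed integer master seed; every stream derives from it.
#' @param n_chroms,chrom_length genome shape (default 3 x 2 Mb).
#' @param island_spacing,island_width,island_cpg_spacing CpG island layout.
#' @param background_cpg_spacing mean background CpG spacing (bp).
#' @param island_meth,background_meth baseline methylation means.
#' @param n_regions planted focal regions (50).
#' @param region_width_meanlog,region_width_sdlog lognormal width model.
#' @param depth_sdlog lognormal SD of the per-region depth factor.
#' @param effects named per-tier effect sizes.
#' @param ko_extra_regions extra regions only hypomethylated in the
#'   knockout tier.
#' @param gene_body_fraction fraction of planted regions placed in gene
#'   bodies.
#' @param noisy_region_fraction fraction of regions planted with high
#'   between-sample variance.
#' @param jitter_concentration,noisy_concentration beta jitter parameters.
#' @param coverage_mean,coverage_size negative-binomial coverage model.
#' @param n_test,n_ref cohort sizes (6 vs 10, mouse-like).
#' @param age_range log-uniform age range.
#' @param n_age_regions regions carrying an age effect instead of a
#'   genotype effect.
#' @param age_slope methylation change per unit log(age) in age regions.
#' @param chain_block,chain_invert_frac,chain_delete_frac chain shuffle
#'   model.
#' @param scrna list of scRNA design fields (see
#'   \code{\link{simulate_scrna}}).
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_chroms = 3L, chrom_length = 2e6,
                       island_spacing = 50000, island_width = 1000,
                       island_cpg_spacing = 12,
                       background_cpg_spacing = 55,
                       island_meth = 0.1, background_meth = 0.9,
                       n_regions = 50L,
                       region_width_meanlog = log(650),
                       region_width_sdlog = 0.35,
                       depth_sdlog = 0.45,
                       effects = c(severe = -0.35, mild = -0.12,
                                   haplo = -0.03, ko = -0.55),
                       ko_extra_regions = 100L,
                       gene_body_fraction = 0.6,
                       noisy_region_fraction = 0.05,
                       jitter_concentration = 200,
                       noisy_concentration = 12,
                       coverage_mean = 18, coverage_size = 8,
                       n_test = 6L, n_ref = 10L,
                       age_range = c(2, 43),
                       n_age_regions = 2L, age_slope = -0.05,
                       chain_block = 50000,
                       chain_invert_frac = 0.1,
                       chain_delete_frac = 0,
                       scrna = list(n_clusters = 4L, genes = 600L,
                                    cells_per_cluster = 150L,
                                    markers_per_cluster = 30L,
                                    marker_fold = 8,
                                    degs_per_cluster = 5L, deg_fold = 4,
                                    mito_gene_fraction = 0.05,
                                    nb_size = 2,
                                    cluster_props = NULL,
                                    qc_violator_fraction = 0.02)) {
  cfg <- as.list(environment())
  stopifnot(cfg$seed == as.integer(cfg$seed), cfg$chrom_length > 0,
            all(cfg$effects <= 0 | names(cfg$effects) == "hyper"))
  class(cfg) <- "sim_config"
  cfg
}

# deterministic sub-seed per stream, kept below 2^31
sub_seed <- function(cfg, offset) (as.integer(cfg$seed) * 1009L + offset) %%
  2147483647L

#' Simulate the CpG landscape, baselines, annotations, and planted truth
#'
#' Islands are hypomethylated (mean ~0.1) and CpG-dense, the background is
#' hypermethylated (mean ~0.9). Planted focal regions are placed on
#' background (methylated) CpG-bearing sequence, non-overlapping, with a
#' configured fraction falling inside gene bodies. Annotations (gene
#' bodies, promoters, TSS windows, enhancers, CpG islands) are written
#' directly.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list: \code{sites} (CpG data.frame), \code{baseline} (per-CpG
#'   methylation), \code{annotations} (GRanges), \code{truth} (planted
#'   regions with depth factors and flags).
#' @export
simulate_genome_cpgs <- function(cfg = sim_config()) {
  set.seed(sub_seed(cfg, 1L))
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  sites <- list()
  island_iv <- list()
  for (ch in chroms) {
    n_isl <- floor(cfg$chrom_length / cfg$island_spacing)
    if (n_isl < 1 && cfg$island_spacing <= cfg$chrom_length)
      stop("chromosome too short for requested islands")
    isl_start <- if (n_isl > 0)
      round(seq_len(n_isl) * cfg$island_spacing -
              cfg$island_spacing / 2) else integer(0)
    # background CpGs: exponential spacing
    n_bg <- ceiling(cfg$chrom_length / cfg$background_cpg_spacing * 1.3)
    bg_pos <- cumsum(pmax(2, round(stats::rexp(n_bg,
                                               1 / cfg$background_cpg_spacing))))
    bg_pos <- bg_pos[bg_pos < cfg$chrom_length - 1]
    isl_pos <- unlist(lapply(isl_start, function(s)
      seq(s, min(s + cfg$island_width, cfg$chrom_length - 2),
          by = cfg$island_cpg_spacing)))
    in_island <- rep(FALSE, length(bg_pos))
    for (s in isl_start)
      in_island <- in_island | (bg_pos >= s & bg_pos < s + cfg$island_width)
    pos <- sort(unique(c(bg_pos[!in_island], isl_pos)))
    isl_flag <- rep(FALSE, length(pos))
    for (s in isl_start)
      isl_flag <- isl_flag | (pos >= s & pos < s + cfg$island_width)
    sites[[ch]] <- data.frame(chrom = ch, start = as.integer(pos),
                              end = as.integer(pos + 1),
                              island = isl_flag)
    island_iv[[ch]] <- data.frame(chrom = rep(ch, length(isl_start)),
                                  start = isl_start,
                                  end = isl_start + cfg$island_width)
  }
  sites <- do.call(rbind, sites)
  rownames(sites) <- NULL
  n <- nrow(sites)
  baseline <- ifelse(sites$island,
                     rbeta(n, cfg$island_meth * 30,
                           (1 - cfg$island_meth) * 30),
                     rbeta(n, cfg$background_meth * 30,
                           (1 - cfg$background_meth) * 30))
  truth <- place_regions(cfg, sites, island_iv)
  ann <- build_annotations(cfg, truth, island_iv)
  list(sites = sites[, c("chrom", "start", "end")],
       island = sites$island, baseline = baseline,
       annotations = ann, truth = truth, chroms = chroms)
}

# Place planted regions on background sequence, non-overlapping, away from
# islands; assign per-region depth factors and flags.
place_regions <- function(cfg, sites, island_iv) {
  total <- cfg$n_regions + cfg$ko_extra_regions + cfg$n_age_regions
  chroms <- names(island_iv)
  placed <- data.frame()
  guard <- 0L
  while (nrow(placed) < total && guard < 50000L) {
    guard <- guard + 1L
    ch <- sample(chroms, 1)
    w <- round(rlnorm(1, cfg$region_width_meanlog, cfg$region_width_sdlog))
    w <- max(w, 120)
    s <- sample.int(cfg$chrom_length - w - 1L, 1)
    iv <- island_iv[[ch]]
    clash_island <- any(iv$start < s + w & iv$end > s)
    clash_placed <- nrow(placed) > 0 &&
      any(placed$chrom == ch & placed$start < s + w + 2000 &
            placed$end > s - 2000)
    cpgs_in <- sum(sites$chrom == ch & sites$start >= s &
                     sites$start < s + w & !sites$island)
    if (!clash_island && !clash_placed && cpgs_in >= 12)
      placed <- rbind(placed, data.frame(chrom = ch, start = s,
                                         end = s + w, n_cpgs = cpgs_in))
  }
  if (nrow(placed) < total)
    stop("could not place ", total, " regions; genome too small")
  placed <- placed[order(placed$chrom, placed$start), ]
  rownames(placed) <- NULL
  placed$region_id <- paste0("region_", seq_len(nrow(placed)))
  set <- sample(c(rep("core", cfg$n_regions),
                  rep("ko_extra", cfg$ko_extra_regions),
                  rep("age", cfg$n_age_regions)))
  placed$role <- set
  placed$depth_factor <- rlnorm(nrow(placed), 0, cfg$depth_sdlog)
  placed$noisy <- FALSE
  core <- which(placed$role == "core")
  n_noisy <- round(cfg$noisy_region_fraction * length(core))
  if (n_noisy > 0)
    placed$noisy[sample(core, n_noisy)] <- TRUE
  placed$in_gene_body <- FALSE
  gb <- sample(seq_len(nrow(placed)),
               round(cfg$gene_body_fraction * nrow(placed)))
  placed$in_gene_body[gb] <- TRUE
  placed
}

build_annotations <- function(cfg, truth, island_iv) {
  rows <- list()
  gidx <- 0L
  # gene bodies hosting planted regions
  for (i in which(truth$in_gene_body)) {
    gidx <- gidx + 1L
    pad_l <- sample(2000:8000, 1)
    pad_r <- sample(2000:8000, 1)
    gs <- max(0, truth$start[i] - pad_l)
    ge <- min(cfg$chrom_length, truth$end[i] + pad_r)
    g <- sprintf("GENE%04d", gidx)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = truth$chrom[i], start = gs, end = ge,
      category = "gene_body", gene = g)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = truth$chrom[i], start = max(0, gs - 2000), end = gs,
      category = "promoter", gene = g)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = truth$chrom[i], start = max(0, gs - 500), end = gs + 500,
      category = "tss", gene = g)
  }
  # background gene bodies and enhancers on a regular lattice
  chroms <- names(island_iv)
  for (ch in chroms) {
    starts <- seq(5000, cfg$chrom_length - 30000, by = 40000)
    for (s in starts) {
      gidx <- gidx + 1L
      g <- sprintf("GENE%04d", gidx)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = s, end = s + 15000,
        category = "gene_body", gene = g)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = s + 20000, end = s + 21000,
        category = "enhancer", gene = NA_character_)
    }
    iv <- island_iv[[ch]]
    if (nrow(iv))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = iv$chrom, start = iv$start, end = iv$end,
        category = "cpg_island", gene = NA_character_)
  }
  ann <- do.call(rbind, rows)
  GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    category = ann$category, gene = ann$gene,
    name = ifelse(is.na(ann$gene), ann$category,
                  paste0(ann$category, ":", ann$gene)))
}

#' Simulate a two-group bisulfite cohort
#'
#' Per CpG per sample, the true methylation is clip(baseline + tier effect
#' inside planted regions + age effect * log(age) in age regions, 0, 1)
#' with per-sample beta jitter; coverage is negative binomial (mean 18) and
#' the methylated count binomial. Test-group samples carry the tier effect
#' scaled by each region's depth factor; reference samples do not.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param genome output of \code{\link{simulate_genome_cpgs}}.
#' @param tier one of \code{names(cfg$effects)}, or \code{"none"} for a
#'   control-vs-control null cohort.
#' @param seed_offset stream offset so repeated cohorts differ.
#' @return list: \code{matrix} (a \code{\link{meth_matrix}}),
#'   \code{metadata} (sample table).
#' @export
simulate_methylation_samples <- function(cfg, genome, tier = "severe",
                                         seed_offset = 0L) {
  set.seed(sub_seed(cfg, 100L + seed_offset))
  stopifnot(tier %in% c(names(cfg$effects), "none"))
  n <- nrow(genome$sites)
  ids <- c(paste0("test_", seq_len(cfg$n_test)),
           paste0("ref_", seq_len(cfg$n_ref)))
  groups <- rep(c("test", "ref"), c(cfg$n_test, cfg$n_ref))
  ages <- exp(runif(length(ids), log(cfg$age_range[1]),
                    log(cfg$age_range[2])))
  sexes <- rep_len(c("M", "F"), length(ids))
  metadata <- data.frame(sample = ids, group = groups, age = ages,
                         sex = sexes, stringsAsFactors = FALSE)
  tr <- genome$truth
  effect_rows <- if (tier == "none") integer(0) else {
    sel <- tr$role == "core" | (tier == "ko" & tr$role == "ko_extra")
    which(sel)
  }
  # per-CpG planted effect for test samples
  cpg_effect <- numeric(n)
  cpg_noisy <- logical(n)
  key_ch <- genome$sites$chrom
  key_pos <- genome$sites$start
  for (i in effect_rows) {
    inr <- key_ch == tr$chrom[i] & key_pos >= tr$start[i] &
      key_pos < tr$end[i]
    cpg_effect[inr] <- cfg$effects[[tier]] * tr$depth_factor[i]
    cpg_noisy[inr] <- tr$noisy[i]
  }
  cpg_age <- numeric(n)
  for (i in which(tr$role == "age")) {
    inr <- key_ch == tr$chrom[i] & key_pos >= tr$start[i] &
      key_pos < tr$end[i]
    cpg_age[inr] <- cfg$age_slope
  }
  ratio <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
  coverage <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  mean_lage <- mean(log(metadata$age))
  for (j in seq_along(ids)) {
    mu <- genome$baseline +
      (if (groups[j] == "test") cpg_effect else 0) +
      cpg_age * (log(ages[j]) - mean_lage)
    mu <- pmin(1 - 1e-6, pmax(1e-6, mu))
    conc <- ifelse(cpg_noisy, cfg$noisy_concentration,
                   cfg$jitter_concentration)
    true_m <- rbeta(n, mu * conc, (1 - mu) * conc)
    cov <- rnbinom(n, size = cfg$coverage_size, mu = cfg$coverage_mean)
    meth <- rbinom(n, cov, true_m)
    coverage[, j] <- cov
    ratio[, j] <- ifelse(cov > 0, meth / cov, NA_real_)
  }
  list(matrix = meth_matrix(genome$sites, ratio, coverage),
       metadata = metadata)
}

#' Write a cohort to per-sample CpG tables plus a metadata TSV
#'
#' Files are in the \code{\link{read_methylation_table}} format (6-column
#' TSV), one per sample, under \code{dir}.
#'
#' @param sim output of \code{\link{simulate_methylation_samples}}.
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat <- sim$matrix
  for (s in mat$samples) {
    cov <- mat$coverage[, s]
    keep <- cov > 0
    meth <- round(mat$ratio[keep, s] * cov[keep])
    tab <- data.frame(mat$sites$chrom[keep], mat$sites$start[keep],
                      mat$sites$end[keep],
                      round(meth / cov[keep], 4), meth, cov[keep] - meth)
    write.table(tab, file.path(dir, paste0(s, ".meth.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  write.table(sim$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate a chain-linked second genome
#'
#' The target genome is a block permutation of the source: each chromosome
#' is cut into \code{chain_block}-sized blocks which are shuffled,
#' optionally inverted, and optionally deleted, then concatenated on a
#' target chromosome. Valid UCSC chain files are produced in both
#' directions along with a truth table mapping every surviving planted
#' region.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param genome output of \code{\link{simulate_genome_cpgs}}.
#' @param dir optional directory; when given, \code{forward.chain} and
#'   \code{reverse.chain} are written there.
#' @return list: \code{forward} and \code{reverse} \code{chain_map}s,
#'   \code{truth} (per planted region: deleted flag and expected target
#'   interval), \code{forward_file}/\code{reverse_file} when written.
#' @export
simulate_chain_pair <- function(cfg, genome, dir = NULL) {
  set.seed(sub_seed(cfg, 500L))
  B <- as.integer(cfg$chain_block)
  blocks <- list()
  for (ch in genome$chroms) {
    starts <- seq(0L, cfg$chrom_length - 1L, by = B)
    blocks[[ch]] <- data.frame(
      chrom = ch, start = starts,
      end = pmin(starts + B, as.integer(cfg$chrom_length)))
  }
  blocks <- do.call(rbind, blocks)
  nb <- nrow(blocks)
  blocks$deleted <- runif(nb) < cfg$chain_delete_frac
  blocks$inverted <- !blocks$deleted & runif(nb) < cfg$chain_invert_frac
  surv <- which(!blocks$deleted)
  order_t <- sample(surv)
  tchrom <- "chrT1"
  tsizes <- blocks$end - blocks$start
  toff <- cumsum(c(0L, tsizes[order_t]))
  tlen <- toff[length(toff)]
  blocks$t_start <- NA_integer_
  blocks$t_start[order_t] <- toff[-length(toff)]
  fwd_lines <- character(0)
  rev_lines <- character(0)
  cid <- 0L
  for (i in surv) {
    cid <- cid + 1L
    sz <- tsizes[i]
    ts <- blocks$t_start[i]
    q_strand <- if (blocks$inverted[i]) "-" else "+"
    q_start <- if (blocks$inverted[i]) tlen - (ts + sz) else ts
    fwd_lines <- c(fwd_lines, sprintf(
      "chain %d %s %d + %d %d %s %d %s %d %d %d",
      1000L + sz, blocks$chrom[i], as.integer(cfg$chrom_length),
      blocks$start[i], blocks$end[i], tchrom, tlen, q_strand,
      q_start, q_start + sz, cid), sz, "")
    # reverse direction: source is the target genome (+ strand), query the
    # original; an inverted block is inverted in this direction too
    r_strand <- q_strand
    r_start <- if (blocks$inverted[i])
      as.integer(cfg$chrom_length) - blocks$end[i] else blocks$start[i]
    rev_lines <- c(rev_lines, sprintf(
      "chain %d %s %d + %d %d %s %d %s %d %d %d",
      1000L + sz, tchrom, tlen, ts, ts + sz, blocks$chrom[i],
      as.integer(cfg$chrom_length), r_strand, r_start, r_start + sz,
      cid), sz, "")
  }
  fwd_file <- rev_file <- NULL
  tf <- tempfile(fileext = ".chain")
  writeLines(fwd_lines, tf)
  forward <- read_chain(tf)
  writeLines(rev_lines, tf)
  reverse <- read_chain(tf)
  unlink(tf)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fwd_file <- file.path(dir, "forward.chain")
    rev_file <- file.path(dir, "reverse.chain")
    writeLines(fwd_lines, fwd_file)
    writeLines(rev_lines, rev_file)
  }
  tr <- genome$truth
  tr$block <- NA_integer_
  tr$deleted <- FALSE
  tr$target_chrom <- NA_character_
  tr$target_start <- NA_integer_
  tr$target_end <- NA_integer_
  for (i in seq_len(nrow(tr))) {
    bi <- which(blocks$chrom == tr$chrom[i] &
                  blocks$start <= tr$start[i] & blocks$end >= tr$end[i])
    if (!length(bi)) {
      # straddles a block boundary: treat as deleted only if either side is
      bi2 <- which(blocks$chrom == tr$chrom[i] &
                     blocks$start < tr$end[i] & blocks$end > tr$start[i])
      tr$deleted[i] <- any(blocks$deleted[bi2])
      next
    }
    tr$block[i] <- bi
    if (blocks$deleted[bi]) {
      tr$deleted[i] <- TRUE
      next
    }
    off <- tr$start[i] - blocks$start[bi]
    w <- tr$end[i] - tr$start[i]
    if (blocks$inverted[bi]) {
      te <- blocks$t_start[bi] + (blocks$end[bi] - tr$start[i])
      tr$target_start[i] <- te - w
      tr$target_end[i] <- te
    } else {
      tr$target_start[i] <- blocks$t_start[bi] + off
      tr$target_end[i] <- blocks$t_start[bi] + off + w
    }
    tr$target_chrom[i] <- tchrom
  }
  list(forward = forward, reverse = reverse, truth = tr,
       forward_file = fwd_file, reverse_file = rev_file,
       blocks = blocks, target_length = tlen)
}

#' Simulate a clustered single-cell count matrix with planted DEGs
#'
#' Two samples (reference and test genotype) with per-cluster
#' negative-binomial counts, marker-gene blocks per cluster, planted DEG
#' genes whose means are multiplied in the test genotype, ~5 percent
#' mitochondrial genes with per-cell mito load drawn so a small tail of
#' cells exceeds the 10 percent QC bar, and a small fraction of cells that
#' deliberately violate the QC minima. Reference profiles are the cluster
#' mean vectors of the reference sample.
#'
#' @param cfg a \code{\link{sim_config}} (fields under \code{cfg$scrna}).
#' @param seed_offset stream offset.
#' @param null_effect when TRUE, planted DEG folds are set to 1 (null).
#' @return list: \code{matrix} (an \code{\link{expr_matrix}}),
#'   \code{reference} (lineage x gene profile matrix), \code{truth}
#'   (planted DEG table).
#' @export
simulate_scrna <- function(cfg = sim_config(), seed_offset = 0L,
                           null_effect = FALSE) {
  sc <- cfg$scrna
  set.seed(sub_seed(cfg, 900L + seed_offset))
  G <- sc$genes
  K <- sc$n_clusters
  n_mito <- max(1L, round(sc$mito_gene_fraction * G))
  gene_names <- c(paste0("mt-", seq_len(n_mito)),
                  sprintf("Gene%04d", seq_len(G - n_mito)))
  mito_genes <- gene_names[seq_len(n_mito)]
  nuclear <- setdiff(gene_names, mito_genes)
  base_mu <- setNames(rlnorm(G, meanlog = 0.3, sdlog = 1.0), gene_names)
  base_mu[mito_genes] <- 0  # mito handled separately per cell
  # marker blocks: disjoint gene sets upweighted per cluster
  markers <- split(nuclear[seq_len(K * sc$markers_per_cluster)],
                   rep(seq_len(K), each = sc$markers_per_cluster))
  # planted DEGs: disjoint from markers
  pool <- setdiff(nuclear, unlist(markers))
  deg_genes <- split(pool[seq_len(K * sc$degs_per_cluster)],
                     rep(seq_len(K), each = sc$degs_per_cluster))
  fold <- if (null_effect) 1 else sc$deg_fold
  truth <- do.call(rbind, lapply(seq_len(K), function(k) data.frame(
    cluster = paste0("cluster", k), gene = deg_genes[[k]], fold = fold,
    stringsAsFactors = FALSE)))
  props <- sc$cluster_props
  if (is.null(props))
    props <- list(ref = rep(1 / K, K), test = rep(1 / K, K))
  counts <- list()
  meta <- list()
  cid <- 0L
  total_cells_per_sample <- K * sc$cells_per_cluster
  for (sample_name in c("ref", "test")) {
    n_by_cluster <- round(props[[sample_name]] * total_cells_per_sample)
    for (k in seq_len(K)) {
      nk <- n_by_cluster[k]
      if (nk == 0) next
      mu <- base_mu
      mu[markers[[k]]] <- mu[markers[[k]]] * sc$marker_fold
      if (sample_name == "test")
        mu[deg_genes[[k]]] <- mu[deg_genes[[k]]] * fold
      m <- matrix(rnbinom(G * nk, size = sc$nb_size, mu = rep(mu, nk)),
                  nrow = G, dimnames = list(gene_names, NULL))
      # per-cell mitochondrial load
      mito_frac <- rbeta(nk, 2, 48)
      tot <- colSums(m)
      mito_tot <- round(tot * mito_frac / (1 - mito_frac))
      for (j in seq_len(nk))
        if (mito_tot[j] > 0)
          m[mito_genes, j] <- stats::rmultinom(1, mito_tot[j],
                                               rep(1, n_mito))
      # deliberate QC violators: heavily downsampled cells
      viol <- runif(nk) < sc$qc_violator_fraction
      if (any(viol))
        m[, viol] <- matrix(rbinom(G * sum(viol), m[, viol, drop = FALSE],
                                   0.03), nrow = G)
      cells <- paste0("cell", cid + seq_len(nk))
      cid <- cid + nk
      colnames(m) <- cells
      counts[[length(counts) + 1L]] <- m
      meta[[length(meta) + 1L]] <- data.frame(
        cell = cells, sample = sample_name,
        group = if (sample_name == "test") "mutant" else "control",
        cluster = paste0("cluster", k), stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, counts)
  meta <- do.call(rbind, meta)
  x <- expr_matrix(counts, meta, mito_genes = mito_genes)
  refcells <- meta$cell[meta$sample == "ref"]
  profiles <- do.call(rbind, lapply(seq_len(K), function(k) {
    cells <- meta$cell[meta$sample == "ref" &
                         meta$cluster == paste0("cluster", k)]
    colMeans(t(counts[, cells, drop = FALSE]))
  }))
  rownames(profiles) <- paste0("cluster", seq_len(K))
  list(matrix = x, reference = profiles, truth = truth)
}
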