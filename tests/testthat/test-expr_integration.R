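# Small deterministic expression fixture: 2 genes are mito, boundary cells
# constructed exactly at the QC thresholds.
make_cells <- function(specs) {
  # specs: list of c(genes_expressed, total_reads, mito_frac)
  G <- 400
  genes <- c("mt-1", "mt-2", sprintf("G%03d", 1:(G - 2)))
  m <- matrix(0L, G, length(specs), dimnames = list(genes, names(specs)))
  for (j in seq_along(specs)) {
    s <- specs[[j]]
    mito_reads <- round(s[2] * s[3])
    nuc_reads <- s[2] - mito_reads
    ng <- s[1] - (mito_reads > 0)  # expressed genes incl mito if present
    nuc_genes <- sample(3:G, ng)
    base <- rep(1L, ng)
    extra <- nuc_reads - ng
    if (extra > 0) base[1] <- base[1] + extra
    m[nuc_genes, j] <- base
    if (mito_reads > 0) m[1, j] <- as.integer(mito_reads)
  }
  md <- data.frame(cell = names(specs), sample = "s1", group = "g1",
                   cluster = "c1", stringsAsFactors = FALSE)
  expr_matrix(m, md, mito_genes = c("mt-1", "mt-2"))
}

test_that("QC boundaries are strict inequalities, exactly as stated", {
  set.seed(2)
  x <- make_cells(list(
    low_genes = c(200, 5000, 0.01),   # fails the gene rule only
    low_reads = c(300, 499, 0),       # fails the read rule only
    boundary = c(250, 500, 0.10),     # exactly at all three: kept
    high_mito = c(300, 2000, 0.12),   # fails the mito rule only
    good = c(350, 3000, 0.02)))
  res <- qc_filter_cells(x)
  kept <- res$matrix$cell_meta$cell
  expect_setequal(kept, c("boundary", "good"))
  rep <- res$report
  expect_equal(rep$removed[rep$rule == "min_genes"], 1L)
  expect_equal(rep$removed[rep$rule == "min_reads"], 1L)
  expect_equal(rep$removed[rep$rule == "max_mito"], 1L)
  # relaxing thresholds never removes more cells (monotone)
  res2 <- qc_filter_cells(x, qc_params(min_genes = 100, min_reads = 100,
                                       max_mito_fraction = 0.5))
  expect_gte(ncol(res2$matrix$counts), ncol(res$matrix$counts))
  # missing mito flags error
  x2 <- x; x2$mito_genes <- character(0)
  expect_error(qc_filter_cells(x2), "mito")
})

test_that("normalization scales cells to exactly 10,000 and is invariant", {
  counts <- matrix(c(1L, 2L, 7L, 2L, 4L, 14L), 3,
                   dimnames = list(c("a", "b", "c"), c("x", "y")))
  md <- data.frame(cell = c("x", "y"), sample = "s", group = "g",
                   cluster = "c1")
  x <- normalize_cells(expr_matrix(counts, md, mito_genes = "a"))
  expect_equal(unname(colSums(x$scaled)), c(10000, 10000))
  expect_equal(x$scaled[, "x"], c(a = 1000, b = 2000, c = 7000))
  # doubling all counts in a cell leaves its normalized vector unchanged
  expect_equal(x$norm[, "x"], x$norm[, "y"])
  expect_equal(unname(x$norm[, "x"]), log1p(c(1000, 2000, 7000)))
})

test_that("cluster composition chi-squared matches hand computation", {
  md <- data.frame(cell = sprintf("c%03d", 1:120),
                   sample = rep(c("s1", "s2"), each = 60),
                   group = rep(c("g1", "g2"), each = 60),
                   cluster = c(rep("A", 50), rep("B", 10),
                               rep("A", 10), rep("B", 50)))
  counts <- matrix(1L, 2, 120, dimnames = list(c("mt-1", "g1"), md$cell))
  x <- expr_matrix(counts, md, "mt-1")
  res <- cluster_composition_test(x)
  expect_equal(res$statistic, 53.33333, tolerance = 1e-6)
  expect_lt(res$p, 1e-12)
  expect_equal(res$statistic, chisq_manual(table(md$cluster, md$sample)),
               tolerance = 1e-10)
  # identical composition: statistic 0, p = 1
  md$cluster <- rep(c("A", "B"), 60)
  x2 <- expr_matrix(counts, md, "mt-1")
  expect_equal(cluster_composition_test(x2)$p, 1)
})

test_that("DEG gates are conjunctive and recover planted fold changes", {
  sims <- 0L
  recovered <- 0L
  for (s in 1:5) {
    cfg <- sim_config(seed = 100 + s)
    sc <- simulate_scrna(cfg)
    x <- normalize_cells(qc_filter_cells(sc$matrix)$matrix)
    degs <- suppressWarnings(cluster_deg_test(x, "mutant", "control"))
    expect_true(all(degs$p <= 0.05))
    expect_true(all(abs(degs$log2_ratio) >= 1))
    truth_key <- paste(sc$truth$cluster, sc$truth$gene)
    got_key <- paste(degs$cluster, degs$gene)
    recovered <- recovered + sum(truth_key %in% got_key)
    sims <- sims + nrow(sc$truth)
  }
  expect_gte(recovered / sims, 0.8)
})

test_that("null scRNA simulation keeps per-cluster false positives low", {
  fp <- c()
  for (s in 1:5) {
    cfg <- sim_config(seed = 200 + s)
    sc <- simulate_scrna(cfg, null_effect = TRUE)
    x <- normalize_cells(qc_filter_cells(sc$matrix)$matrix)
    degs <- suppressWarnings(cluster_deg_test(x, "mutant", "control"))
    for (cl in unique(x$cell_meta$cluster))
      fp <- c(fp, sum(degs$cluster == cl) / nrow(x$counts))
  }
  expect_lte(max(fp), 0.05)
})

test_that("recurrent_degs classifies concordance across clusters", {
  degs <- data.frame(
    cluster = c("c1", "c2", "c3", "c1", "c2", "c1"),
    gene = c("RASIP1", "RASIP1", "RASIP1", "HOXB2", "HOXB2", "ONLY1"),
    direction = c("up", "up", "up", "up", "down", "up"))
  rec <- recurrent_degs(degs)
  expect_setequal(rec$gene, c("RASIP1", "HOXB2"))
  expect_true(rec$concordant[rec$gene == "RASIP1"])
  expect_false(rec$concordant[rec$gene == "HOXB2"])
  expect_equal(rec$n_clusters[rec$gene == "RASIP1"], 3L)
  expect_equal(nrow(recurrent_degs(degs[degs$gene == "ONLY1", ])), 0L)
})

test_that("expressing_fraction_test equals hypergeometric enumeration", {
  md <- data.frame(cell = sprintf("c%03d", 1:200),
                   sample = rep(c("s1", "s2"), each = 100),
                   group = rep(c("ctrl", "mut"), each = 100),
                   cluster = "c1")
  counts <- matrix(0L, 2, 200, dimnames = list(c("mt-1", "RASIP1"),
                                               md$cell))
  counts["RASIP1", c(1, 101:115)] <- 1L  # 1/100 vs 15/100 expressing
  x <- expr_matrix(counts, md, "mt-1")
  res <- expressing_fraction_test(x, "RASIP1", groups = c("ctrl", "mut"))
  expect_equal(unname(res$fractions), c(0.01, 0.15))
  expect_equal(res$p, fisher_enum(res$table), tolerance = 1e-9)
  expect_lt(res$p, 0.001)

  # random 2x2 tables vs enumeration
  set.seed(13)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 20), 2)
    expect_equal(fisher.test(tab)$p.value, fisher_enum(tab),
                 tolerance = 1e-9)
  }
  # zero expressing in both groups: p = 1
  counts2 <- counts; counts2["RASIP1", ] <- 0L
  x2 <- expr_matrix(counts2, md, "mt-1")
  expect_equal(expressing_fraction_test(x2, "RASIP1",
                                        groups = c("ctrl", "mut"))$p, 1)
})

test_that("link_degs_to_dmrs distances match brute force", {
  degs <- data.frame(gene = c("A", "B", "C"), cluster = "c1",
                     direction = "up")
  gi <- data.frame(gene = c("A", "B"), chrom = "chr1",
                   start = c(1000L, 100000L), end = c(5000L, 110000L))
  dmrs <- data.frame(chrom = "chr1", start = 5500L, end = 6000L)
  res <- link_degs_to_dmrs(degs, gi, dmrs)
  tab <- res$table
  expect_equal(tab$distance[tab$gene == "A"], 500)
  expect_true(tab$linked[tab$gene == "A"])
  expect_false(tab$linked[tab$gene == "B"])  # ~89 kb away
  expect_true(tab$no_interval[tab$gene == "C"])
  expect_equal(res$n_linked, 1L)
  expect_equal(res$n_total, 3L)

  set.seed(19)
  for (i in 1:10) {
    ng <- sample(2:20, 1); nd <- sample(1:20, 1)
    gi2 <- data.frame(gene = paste0("g", 1:ng), chrom = "chr1",
                      start = sample.int(1e5, ng))
    gi2$end <- gi2$start + sample.int(5000, ng)
    dm2 <- data.frame(chrom = "chr1", start = sample.int(1e5, nd))
    dm2$end <- dm2$start + sample.int(1000, nd)
    degs2 <- data.frame(gene = gi2$gene, cluster = "c", direction = "up")
    got <- link_degs_to_dmrs(degs2, gi2, dm2)$table
    expect_equal(got$distance[match(gi2$gene, got$gene)],
                 nearest_brute(gi2, dm2))
  }
})

test_that("knn lineage annotation recovers cluster labels", {
  cfg <- sim_config(seed = 77)
  sc <- simulate_scrna(cfg)
  x <- qc_filter_cells(sc$matrix)$matrix
  labels <- knn_lineage_annotate(x, sc$reference)
  agree <- mean(labels == x$cell_meta$cluster)
  expect_gte(agree, 0.99)
  # all-zero cell is unassigned
  x0 <- x
  x0$counts[, 1] <- 0L
  expect_equal(unname(knn_lineage_annotate(x0, sc$reference)[1]),
               "unassigned")
  # too few shared genes errors
  expect_error(knn_lineage_annotate(x, sc$reference[, 1:10]), "shared")
})

test_that("cross-species concordance is case-insensitive on symbols", {
  h <- data.frame(gene = c("RASIP1", "HOXB2", "ZZZ3"),
                  direction = c("up", "down", "up"), cluster = "c1")
  m <- data.frame(gene = c("Rasip1", "Hoxb2"),
                  direction = c("up", "up"), cluster = "k1")
  res <- cross_species_deg_concordance(h, m)
  expect_equal(res$n_concordant, 1L)  # Rasip1 up/up; Hoxb2 down vs up
  expect_equal(res$percent, 100 / 3)
  none <- cross_species_deg_concordance(
    h, data.frame(gene = "OTHER", direction = "up", cluster = "k"))
  expect_equal(none$n_concordant, 0L)
})

test_that("MTX bundle and dense TSV readers round-trip counts", {
  cfg <- sim_config(seed = 88, scrna = list(
    n_clusters = 2L, genes = 80L, cells_per_cluster = 15L,
    markers_per_cluster = 10L, marker_fold = 8, degs_per_cluster = 2L,
    deg_fold = 4, mito_gene_fraction = 0.05, nb_size = 2,
    cluster_props = NULL, qc_violator_fraction = 0))
  sc <- simulate_scrna(cfg)
  d <- withr::local_tempdir()
  Matrix::writeMM(Matrix::Matrix(sc$matrix$counts, sparse = TRUE),
                  file.path(d, "matrix.mtx"))
  writeLines(rownames(sc$matrix$counts), file.path(d, "features.tsv"))
  writeLines(colnames(sc$matrix$counts), file.path(d, "barcodes.tsv"))
  write.table(sc$matrix$cell_meta, file.path(d, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  x <- read_expression(d, file.path(d, "cells.tsv"))
  expect_equal(unname(as.matrix(x$counts)), unname(sc$matrix$counts))
  expect_true(length(x$mito_genes) > 0)

  ftsv <- file.path(d, "dense.tsv")
  write.table(as.data.frame(sc$matrix$counts), ftsv, sep = "\t",
              quote = FALSE)
  x2 <- read_expression(ftsv, file.path(d, "cells.tsv"))
  expect_equal(unname(x2$counts), unname(sc$matrix$counts))
})

test_that("a 14%->5% composition shift is detected at 3000 cells/sample", {
  cfg <- sim_config(seed = 55, scrna = list(
    n_clusters = 4L, genes = 200L, cells_per_cluster = 750L,
    markers_per_cluster = 10L, marker_fold = 8, degs_per_cluster = 2L,
    deg_fold = 4, mito_gene_fraction = 0.05, nb_size = 2,
    cluster_props = list(ref = c(0.14, 0.30, 0.30, 0.26),
                         test = c(0.05, 0.33, 0.33, 0.29)),
    qc_violator_fraction = 0))
  sc <- simulate_scrna(cfg)
  res <- cluster_composition_test(sc$matrix)
  expect_lt(res$p, 0.0001)
  expect_equal(res$fractions["cluster1", "ref"], 14, tolerance = 0.01)
  expect_equal(res$fractions["cluster1", "test"], 5, tolerance = 0.03)
})
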