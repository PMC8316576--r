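# ---------------------------------------------------------------------------
# Single-cell expression integration: QC, depth normalization, per-cluster
# differential expression, recurrent genes, composition and
# expressing-fraction tests, lineage annotation, and DEG<->DMR proximity.
# ---------------------------------------------------------------------------

#' Single-cell expression container
#'
#' @param counts genes x cells matrix (dense or \code{dgCMatrix}) of
#'   non-negative integer counts, with gene and cell names.
#' @param cell_meta data.frame with \code{cell}, \code{sample},
#'   \code{group}, \code{cluster} columns, one row per cell.
#' @param mito_genes character vector of mitochondrial gene names.
#' @param gene_intervals optional data.frame (gene, chrom, start, end) of
#'   gene-body intervals for DMR linking.
#' @return list of class \code{expr_matrix}.
#' @export
expr_matrix <- function(counts, cell_meta, mito_genes = character(0),
                        gene_intervals = NULL) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            all(c("cell", "sample", "group", "cluster") %in%
                  names(cell_meta)))
  if (any(counts < 0)) stop("negative counts")
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$cell), ]
  if (anyNA(cell_meta$cell)) stop("cells missing from metadata")
  structure(list(counts = counts, cell_meta = cell_meta,
                 mito_genes = intersect(mito_genes, rownames(counts)),
                 gene_intervals = gene_intervals,
                 norm = NULL),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d cells, %d cluster(s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$cluster))))
  invisible(x)
}

#' Single-cell QC parameters
#'
#' Cells are removed when they have fewer than \code{min_genes} expressed
#' genes, less than \code{min_reads} total reads, or more than
#' \code{max_mito_fraction} mitochondrial transcripts — strict inequalities
#' exactly as stated, so a cell at precisely 250 genes, 500 reads, and 10
#' percent mitochondrial reads is kept.
#'
#' @param min_genes default 250.
#' @param min_reads default 500.
#' @param max_mito_fraction default 0.10.
#' @param target_depth scaling depth for normalization, default 10000.
#' @return list of class \code{qc_params}.
#' @export
qc_params <- function(min_genes = 250L, min_reads = 500L,
                      max_mito_fraction = 0.10, target_depth = 10000) {
  p <- list(min_genes = as.integer(min_genes),
            min_reads = as.integer(min_reads),
            max_mito_fraction = max_mito_fraction,
            target_depth = target_depth)
  stopifnot(all(unlist(p) > 0))
  class(p) <- "qc_params"
  p
}

#' Filter cells on QC rules
#'
#' @param x an \code{\link{expr_matrix}} with mitochondrial genes flagged.
#' @param params a \code{\link{qc_params}}.
#' @return list: \code{matrix} (filtered \code{expr_matrix}) and
#'   \code{report} (per-rule removal counts; a cell can fail several).
#' @export
qc_filter_cells <- function(x, params = qc_params()) {
  if (!length(x$mito_genes))
    stop("no mitochondrial genes flagged; QC requires mito flags")
  total <- Matrix::colSums(x$counts)
  n_genes <- Matrix::colSums(x$counts > 0)
  mito <- Matrix::colSums(x$counts[x$mito_genes, , drop = FALSE])
  mito_frac <- ifelse(total > 0, mito / total, 1)
  fail_genes <- n_genes < params$min_genes
  fail_reads <- total < params$min_reads
  fail_mito <- mito_frac > params$max_mito_fraction
  drop <- fail_genes | fail_reads | fail_mito
  y <- x
  y$counts <- x$counts[, !drop, drop = FALSE]
  y$cell_meta <- x$cell_meta[!drop, , drop = FALSE]
  y$norm <- NULL
  list(matrix = y,
       report = data.frame(rule = c("min_genes", "min_reads", "max_mito"),
                           removed = c(sum(fail_genes), sum(fail_reads),
                                       sum(fail_mito)),
                           total_removed = sum(drop)))
}

#' Depth-normalize and log-transform counts
#'
#' Per cell, counts are scaled so the cell sums to \code{target_depth}
#' (exactly, before the log), then transformed with log(1 + x) (natural
#' log). The scaled pre-log values are kept alongside for fold-change
#' computation.
#'
#' @param x an \code{\link{expr_matrix}} after QC.
#' @param target_depth constant depth, default 10000.
#' @return The \code{expr_matrix} with \code{$norm} (log values) and
#'   \code{$scaled} (pre-log values) matrices attached.
#' @export
normalize_cells <- function(x, target_depth = 10000) {
  total <- Matrix::colSums(x$counts)
  if (any(total == 0))
    stop("zero-total cell present; run qc_filter_cells first")
  scaled <- sweep(as.matrix(x$counts), 2, target_depth / total, `*`)
  x$scaled <- scaled
  x$norm <- log1p(scaled)
  x$target_depth <- target_depth
  x
}

#' Chi-squared test of cluster composition between two samples
#'
#' Pearson chi-squared (no continuity correction) on the clusters x sample
#' contingency table, plus each cluster's percent of total cells per
#' sample. Clusters absent from both samples are dropped.
#'
#' @param x an \code{\link{expr_matrix}} with exactly two samples.
#' @return list: statistic, df, p, and a per-cluster fraction table.
#' @export
cluster_composition_test <- function(x) {
  samples <- unique(x$cell_meta$sample)
  if (length(samples) != 2) stop("composition test needs exactly 2 samples")
  tab <- table(x$cell_meta$cluster, x$cell_meta$sample)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  frac <- sweep(tab, 2, colSums(tab), `/`) * 100
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, fractions = as.data.frame.matrix(frac))
}

#' Per-cluster differential expression between genotypes
#'
#' Within each cluster, each gene is tested with a Welch two-sided t-test
#' on log-normalized values between the test and reference groups (the
#' two-group reduction of a one-way ANOVA). The log2 ratio uses
#' depth-scaled (pre-log) group means with a pseudo-count of 1:
#' log2((mean_test + 1) / (mean_ref + 1)). A gene is emitted only if
#' p <= \code{max_p} AND |log2 ratio| >= \code{min_log2}, both gates
#' conjunctive. Clusters with fewer than \code{min_cells} cells in either
#' group are skipped with a warning. A BH-adjusted column is added for
#' reference but is not part of the gate.
#'
#' @param x a normalized \code{\link{expr_matrix}}.
#' @param test_group,ref_group genotype labels in \code{cell_meta$group}.
#' @param max_p raw p ceiling (0.05).
#' @param min_log2 |log2 ratio| floor (1).
#' @param min_cells minimum cells per group per cluster (10).
#' @return data.frame of DEG records: cluster, gene, log2_ratio, p, q,
#'   direction, expressing fractions per group.
#' @export
cluster_deg_test <- function(x, test_group, ref_group, max_p = 0.05,
                             min_log2 = 1, min_cells = 10L) {
  if (is.null(x$norm)) stop("run normalize_cells first")
  md <- x$cell_meta
  clusters <- sort(unique(md$cluster))
  out <- list()
  for (cl in clusters) {
    ti <- which(md$cluster == cl & md$group == test_group)
    ri <- which(md$cluster == cl & md$group == ref_group)
    if (length(ti) < min_cells || length(ri) < min_cells) {
      warning("cluster ", cl, " skipped: fewer than ", min_cells,
              " cells in a group")
      next
    }
    nt <- x$norm[, ti, drop = FALSE]
    nr <- x$norm[, ri, drop = FALSE]
    st <- x$scaled[, ti, drop = FALSE]
    sr <- x$scaled[, ri, drop = FALSE]
    p <- row_welch_p(nt, nr)
    l2r <- log2((rowMeans(st) + 1) / (rowMeans(sr) + 1))
    keep <- !is.na(p) & p <= max_p & abs(l2r) >= min_log2
    if (!any(keep)) next
    genes <- rownames(x$norm)[keep]
    out[[length(out) + 1L]] <- data.frame(
      cluster = cl, gene = genes, log2_ratio = l2r[keep], p = p[keep],
      direction = ifelse(l2r[keep] > 0, "up", "down"),
      frac_expr_test = rowMeans(st[keep, , drop = FALSE] > 0),
      frac_expr_ref = rowMeans(sr[keep, , drop = FALSE] > 0),
      stringsAsFactors = FALSE)
  }
  degs <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster = character(0), gene = character(0),
               log2_ratio = numeric(0), p = numeric(0),
               direction = character(0), frac_expr_test = numeric(0),
               frac_expr_ref = numeric(0))
  degs$q <- p.adjust(degs$p, method = "BH")
  rownames(degs) <- NULL
  degs
}

# Vectorized Welch t-test p-values over matrix rows.
row_welch_p <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  p[se2 == 0 & ma == mb] <- 1
  p
}

#' Genes dysregulated in two or more clusters
#'
#' @param degs DEG records from \code{\link{cluster_deg_test}}.
#' @return data.frame per recurrent gene: clusters, per-cluster directions,
#'   n_clusters, concordant flag (all directions equal).
#' @export
recurrent_degs <- function(degs) {
  if (!nrow(degs))
    return(data.frame(gene = character(0), n_clusters = integer(0),
                      directions = character(0), concordant = logical(0)))
  sp <- split(degs, degs$gene)
  sp <- sp[vapply(sp, function(d) length(unique(d$cluster)) >= 2, TRUE)]
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    gene = d$gene[1], n_clusters = length(unique(d$cluster)),
    directions = paste(d$direction[order(d$cluster)], collapse = ","),
    concordant = length(unique(d$direction)) == 1,
    stringsAsFactors = FALSE)))
  if (is.null(out))
    return(data.frame(gene = character(0), n_clusters = integer(0),
                      directions = character(0), concordant = logical(0)))
  rownames(out) <- NULL
  out[order(-out$n_clusters, out$gene), ]
}

#' Fisher exact test on the fraction of expressing cells
#'
#' Expressing means count > 0. Two-sided Fisher exact test on the 2x2
#' expressing/non-expressing x group table over the given clusters.
#'
#' @param x an \code{\link{expr_matrix}}.
#' @param gene gene name.
#' @param groups two group labels (default: all groups present).
#' @param clusters optional cluster subset.
#' @return list: p, per-group expressing fractions, the 2x2 table.
#' @export
expressing_fraction_test <- function(x, gene, groups = NULL,
                                     clusters = NULL) {
  if (!gene %in% rownames(x$counts)) stop("gene not present: ", gene)
  md <- x$cell_meta
  sel <- rep(TRUE, nrow(md))
  if (!is.null(clusters)) sel <- md$cluster %in% clusters
  if (is.null(groups)) groups <- unique(md$group)
  stopifnot(length(groups) == 2)
  expr <- as.numeric(x$counts[gene, ]) > 0
  tab <- matrix(0L, 2, 2, dimnames = list(groups, c("expr", "nonexpr")))
  for (i in 1:2) {
    gi <- sel & md$group == groups[i]
    if (!any(gi)) stop("empty cell subset for group ", groups[i])
    tab[i, ] <- c(sum(expr[gi]), sum(!expr[gi]))
  }
  list(p = fisher.test(tab)$p.value,
       fractions = setNames(tab[, 1] / rowSums(tab), groups),
       table = tab)
}

#' Link differentially expressed genes to nearby DMRs
#'
#' Per unique DEG gene, the edge-to-edge distance from its gene body to the
#' nearest DMR; a gene is linked iff the distance is at most \code{k}
#' (overlap counts as 0). Genes without an interval are unlinked and
#' flagged.
#'
#' @param degs DEG records (needs a \code{gene} column).
#' @param gene_intervals data.frame: gene, chrom, start, end.
#' @param dmrs DMR set or region data.frame.
#' @param k proximity radius in bp (default 10000).
#' @return list: \code{table} (per-gene distances and linked flag),
#'   \code{n_linked}, \code{n_total}.
#' @export
link_degs_to_dmrs <- function(degs, gene_intervals, dmrs, k = 10000) {
  genes <- unique(degs$gene)
  gi <- gene_intervals[match(genes, gene_intervals$gene), ]
  have <- !is.na(gi$chrom)
  out <- data.frame(gene = genes, distance = Inf, linked = FALSE,
                    no_interval = !have, stringsAsFactors = FALSE)
  ddf <- as.data.frame(dmrs)
  if (any(have) && nrow(ddf)) {
    al <- align_seqlevels(df_to_gr(gi[have, ]), df_to_gr(ddf))
    dtn <- GenomicRanges::distanceToNearest(al[[1]], al[[2]],
                                            ignore.strand = TRUE)
    d <- rep(Inf, sum(have))
    d[S4Vectors::queryHits(dtn)] <- S4Vectors::mcols(dtn)$distance
    out$distance[have] <- d
    out$linked <- out$distance <= k
  }
  list(table = out, n_linked = sum(out$linked), n_total = length(genes))
}

#' Annotate cells by nearest reference expression profile
#'
#' Per cell, the Spearman correlation to each reference lineage profile
#' over shared genes; the label is the majority among the \code{k} highest
#' correlations (default k = 1, nearest centroid), ties broken by higher
#' mean correlation. Cells with undefined correlations (e.g. all-zero) are
#' labeled \code{"unassigned"}.
#'
#' @param x a normalized \code{\link{expr_matrix}}.
#' @param reference lineage x gene matrix of mean expression profiles.
#' @param k number of nearest profiles to vote (default 1).
#' @param min_shared minimum shared genes required (50).
#' @return character vector of per-cell lineage labels.
#' @export
knn_lineage_annotate <- function(x, reference, k = 1L, min_shared = 50L) {
  shared <- intersect(colnames(reference), rownames(x$counts))
  if (length(shared) < min_shared)
    stop("only ", length(shared), " shared genes; need >= ", min_shared)
  expr <- as.matrix(x$counts[shared, , drop = FALSE])
  refm <- t(reference[, shared, drop = FALSE])
  cors <- suppressWarnings(cor(expr, refm, method = "spearman"))
  apply(cors, 1, function(r) {
    if (all(is.na(r))) return("unassigned")
    top <- order(r, decreasing = TRUE)[seq_len(min(k, length(r)))]
    votes <- table(rownames(reference)[top])
    winners <- names(votes)[votes == max(votes)]
    if (length(winners) == 1) return(winners)
    means <- vapply(winners, function(w)
      mean(r[rownames(reference) %in% w], na.rm = TRUE), 0)
    winners[which.max(means)]
  })
}

#' Cross-species DEG concordance by gene name
#'
#' Genes present in both DEG sets under a case-insensitive symbol match; a
#' gene is concordant iff any cluster-level direction matches between
#' species. The percent is over unique genes of the first (human) set.
#'
#' @param degs_a,degs_b DEG record data.frames (gene, direction).
#' @return list: per-gene table, n_concordant, percent of A's genes.
#' @export
cross_species_deg_concordance <- function(degs_a, degs_b) {
  ga <- unique(degs_a$gene)
  key_b <- toupper(degs_b$gene)
  tab <- do.call(rbind, lapply(ga, function(g) {
    db <- degs_b[key_b == toupper(g), , drop = FALSE]
    if (!nrow(db))
      return(data.frame(gene = g, shared = FALSE, concordant = FALSE))
    da <- degs_a[degs_a$gene == g, , drop = FALSE]
    data.frame(gene = g, shared = TRUE,
               concordant = length(intersect(unique(da$direction),
                                             unique(db$direction))) > 0)
  }))
  list(table = tab, n_concordant = sum(tab$concordant),
       percent = if (length(ga)) 100 * sum(tab$concordant) / length(ga)
       else NA_real_)
}

#' Read a cell x gene matrix from an MTX triplet bundle or dense TSV
#'
#' \code{path} may be a directory holding \code{matrix.mtx},
#' \code{features.tsv}, \code{barcodes.tsv} (genes as MTX rows), or a dense
#' TSV with genes in rows and cells in columns.
#'
#' @param path bundle directory or TSV path.
#' @param cell_meta_path TSV with cell, sample, group, cluster columns.
#' @param mito_prefix gene-name prefix marking mitochondrial genes
#'   (default \code{"mt-"}, case-insensitive).
#' @return An \code{\link{expr_matrix}}.
#' @export
read_expression <- function(path, cell_meta_path,
                            mito_prefix = "mt-") {
  if (dir.exists(path)) {
    counts <- Matrix::readMM(file.path(path, "matrix.mtx"))
    feats <- readLines(file.path(path, "features.tsv"))
    cells <- readLines(file.path(path, "barcodes.tsv"))
    rownames(counts) <- vapply(strsplit(feats, "\t"), `[`, "", 1)
    colnames(counts) <- cells
  } else {
    tab <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                      check.names = FALSE)
    counts <- as.matrix(tab)
  }
  md <- read.table(cell_meta_path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  mito <- rownames(counts)[startsWith(tolower(rownames(counts)),
                                      tolower(mito_prefix))]
  expr_matrix(counts, md, mito_genes = mito)
}
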