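# ---------------------------------------------------------------------------
# Annotation intersection: fraction of features containing a DMR, per-sample
# per-category mean methylation, and nearest-feature distances. All overlap
# semantics are half-open with at least 1 bp of shared sequence.
# ---------------------------------------------------------------------------

#' Fraction of annotated features containing at least one DMR
#'
#' A feature "contains" a DMR iff they share at least 1 bp. Per category the
#' fraction of features with a DMR is computed, and every pair of categories
#' is compared with a two-sided chi-squared test on the 2x2 table
#' (with/without DMR x category), switching to Fisher's exact test when any
#' expected cell is below 5; pairwise p-values are BH-adjusted.
#'
#' @param annotations \code{GRanges} from \code{\link{read_annotations}}.
#' @param dmrs a \code{dmr_set} or region data.frame (chrom, start, end).
#' @return list with \code{enrichment} (per-category data.frame) and
#'   \code{pairwise} (data.frame of pairwise tests).
#' @export
features_containing_dmrs <- function(annotations, dmrs) {
  ddf <- as.data.frame(dmrs)
  categories <- unique(as.character(annotations$category))
  if (nrow(ddf)) {
    al <- align_seqlevels(annotations, df_to_gr(ddf))
    hit <- GenomicRanges::countOverlaps(al[[1]], al[[2]],
                                        minoverlap = 1L) > 0
  } else {
    hit <- rep(FALSE, length(annotations))
  }
  enr <- do.call(rbind, lapply(categories, function(cg) {
    sel <- annotations$category == cg
    data.frame(category = cg, n_features = sum(sel),
               n_features_with_dmr = sum(hit & sel),
               fraction = if (sum(sel)) sum(hit & sel) / sum(sel)
               else NA_real_)
  }))
  pairs <- if (length(categories) >= 2) combn(categories, 2) else
    matrix(character(0), 2, 0)
  pw <- data.frame(category1 = character(0), category2 = character(0),
                   p = numeric(0), test = character(0))
  for (j in seq_len(ncol(pairs))) {
    a <- enr[enr$category == pairs[1, j], ]
    b <- enr[enr$category == pairs[2, j], ]
    if (a$n_features == 0 || b$n_features == 0) next
    tab <- matrix(c(a$n_features_with_dmr,
                    a$n_features - a$n_features_with_dmr,
                    b$n_features_with_dmr,
                    b$n_features - b$n_features_with_dmr),
                  nrow = 2, byrow = TRUE)
    if (sum(tab) == 0 || all(tab[, 1] == 0)) {
      p <- 1; test <- "none"
    } else {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        p <- fisher.test(tab)$p.value; test <- "fisher"
      } else {
        p <- chisq.test(tab, correct = FALSE)$p.value; test <- "chisq"
      }
    }
    pw <- rbind(pw, data.frame(category1 = pairs[1, j],
                               category2 = pairs[2, j], p = p, test = test))
  }
  pw$q <- p.adjust(pw$p, method = "BH")
  list(enrichment = enr, pairwise = pw)
}

#' Per-sample mean methylation by annotation category
#'
#' For each sample and category: the unweighted mean ratio over covered
#' CpGs lying inside that category's intervals (each CpG counted once even
#' if it lies in several features of the category). With
#' \code{cpg_subset = "dmr_only"} the mean is restricted to CpGs also
#' falling inside a DMR.
#'
#' @param mat a \code{\link{meth_matrix}}.
#' @param annotations \code{GRanges} with a \code{category} column.
#' @param cpg_subset \code{"all"} or \code{"dmr_only"}.
#' @param dmrs DMR set, required for \code{dmr_only}.
#' @return data.frame: sample, category, mean_methylation (NA when a
#'   category holds no covered CpG).
#' @export
region_mean_methylation <- function(mat, annotations,
                                    cpg_subset = c("all", "dmr_only"),
                                    dmrs = NULL) {
  cpg_subset <- match.arg(cpg_subset)
  sites_gr <- df_to_gr(mat$sites)
  in_dmr <- rep(TRUE, nrow(mat$sites))
  if (cpg_subset == "dmr_only") {
    if (is.null(dmrs)) stop("dmr_only requires a DMR set")
    ddf <- as.data.frame(dmrs)
    in_dmr <- if (nrow(ddf)) {
      al <- align_seqlevels(sites_gr, df_to_gr(ddf))
      GenomicRanges::countOverlaps(al[[1]], al[[2]]) > 0
    } else rep(FALSE, nrow(mat$sites))
  }
  categories <- unique(as.character(annotations$category))
  out <- expand.grid(sample = mat$samples, category = categories,
                     stringsAsFactors = FALSE)
  out$mean_methylation <- NA_real_
  for (cg in categories) {
    al <- align_seqlevels(sites_gr, annotations[annotations$category == cg])
    in_cat <- GenomicRanges::countOverlaps(al[[1]], al[[2]]) > 0
    rows <- which(in_cat & in_dmr)
    if (!length(rows)) next
    mm <- colMeans(mat$ratio[rows, , drop = FALSE], na.rm = TRUE)
    mm[is.nan(mm)] <- NA_real_
    out$mean_methylation[out$category == cg] <- mm[out$sample[out$category ==
                                                                cg]]
  }
  out
}

# Edge-to-edge distance between two half-open intervals on one chromosome;
# overlap gives 0.
edge_distance <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

#' Distance from each DMR to the nearest feature of a category
#'
#' Edge-to-edge distance to the nearest same-chromosome feature; overlapping
#' features give distance 0; a chromosome with no feature gives Inf with a
#' flag.
#'
#' @param dmrs DMR set or region data.frame.
#' @param annotations \code{GRanges}.
#' @param category annotation category to search (default: all).
#' @return data.frame: chrom, start, end, distance, no_feature flag.
#' @export
nearest_feature_distance <- function(dmrs, annotations, category = NULL) {
  ddf <- as.data.frame(dmrs)
  feats <- if (is.null(category)) annotations else
    annotations[annotations$category == category]
  out <- data.frame(chrom = ddf$chrom, start = ddf$start, end = ddf$end,
                    distance = Inf, no_feature = TRUE)
  if (!nrow(ddf) || !length(feats)) return(out)
  al <- align_seqlevels(df_to_gr(ddf), feats)
  dtn <- GenomicRanges::distanceToNearest(al[[1]], al[[2]],
                                          ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(dtn)
  out$distance[qi] <- S4Vectors::mcols(dtn)$distance
  out$no_feature[qi] <- FALSE
  out
}
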