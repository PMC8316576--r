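#' @importFrom stats p.adjust sd cor lm coef pt pnorm qnorm rbinom rnbinom
#'   rbeta rnorm runif rlnorm rexp rmultinom complete.cases fisher.test
#'   chisq.test t.test wilcox.test setNames
#' @importFrom utils read.table write.table head tail combn
#' @importFrom methods is
NULL

# ---------------------------------------------------------------------------
# Core container: per-CpG methylation ratios and coverages across samples.
# Coordinates are 0-based half-open; each site is the 1 bp interval at the C
# of a strand-collapsed CpG.
# ---------------------------------------------------------------------------

#' Construct a methylation matrix
#'
#' Holds per-CpG methylation ratios and read coverages for one or more
#' samples. Sites are sorted by (chrom, start); a ratio is \code{NA} exactly
#' where coverage is zero (a CpG not observed in a sample is missing, not
#' unmethylated).
#'
#' @param sites data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open, \code{end == start + 1}).
#' @param ratio numeric matrix, sites x samples, values in [0, 1] or NA.
#' @param coverage integer matrix, sites x samples, non-negative.
#' @return An object of class \code{meth_matrix}.
#' @export
meth_matrix <- function(sites, ratio, coverage) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "start", "end") %in% names(sites)))
  ratio <- as.matrix(ratio)
  coverage <- as.matrix(coverage)
  if (nrow(sites) != nrow(ratio) || !all(dim(ratio) == dim(coverage)))
    stop("sites, ratio and coverage dimensions disagree")
  if (is.null(colnames(ratio))) stop("ratio matrix needs sample column names")
  sites$start <- as.integer(sites$start)
  sites$end <- as.integer(sites$end)
  if (nrow(sites)) {
    if (any(sites$end != sites$start + 1L))
      stop("CpG sites must be 1 bp intervals (end == start + 1)")
    if (any(sites$start < 0L)) stop("negative coordinates")
    o <- order(sites$chrom, sites$start)
    if (is.unsorted(o)) {
      sites <- sites[o, , drop = FALSE]
      ratio <- ratio[o, , drop = FALSE]
      coverage <- coverage[o, , drop = FALSE]
    }
    if (anyDuplicated(paste0(sites$chrom, ":", sites$start)))
      stop("duplicate CpG positions")
  }
  bad <- is.na(ratio) != (coverage == 0)
  if (any(bad, na.rm = TRUE))
    stop("ratio must be NA exactly where coverage is zero")
  if (any(ratio < 0 | ratio > 1, na.rm = TRUE))
    stop("ratios outside [0, 1]")
  rownames(sites) <- NULL
  structure(list(sites = sites, ratio = ratio, coverage = coverage,
                 samples = colnames(ratio)),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d CpGs x %d samples (%s)\n",
              nrow(x$sites), length(x$samples),
              paste(unique(x$sites$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) c(nrow(x$sites), length(x$samples))

#' Read a single-sample per-CpG methylation table
#'
#' Expects a 6-column TSV (bedGraph-descended): chrom, start, end, ratio,
#' methylated count, unmethylated count. The ratio column is cross-checked
#' against meth/(meth+unmeth) with an absolute tolerance of 0.01 to tolerate
#' printed rounding. Gzip input is handled transparently.
#'
#' @param path path to the TSV (optionally .gz).
#' @param sample_id sample name for the single column.
#' @return A one-sample \code{\link{meth_matrix}}.
#' @export
read_methylation_table <- function(path, sample_id) {
  stopifnot(length(sample_id) == 1L)
  tab <- tryCatch(
    read.table(path, sep = "\t", header = FALSE,
               col.names = c("chrom", "start", "end", "ratio",
                             "meth", "unmeth"),
               colClasses = c("character", "integer", "integer",
                              "numeric", "integer", "integer")),
    error = function(e) {
      # empty file is a legitimate degenerate input
      if (grepl("no lines available", conditionMessage(e)))
        return(NULL)
      stop(sprintf("parse error in %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  if (is.null(tab) || nrow(tab) == 0L) {
    empty <- matrix(numeric(0), 0, 1, dimnames = list(NULL, sample_id))
    return(meth_matrix(
      data.frame(chrom = character(0), start = integer(0), end = integer(0)),
      empty, empty))
  }
  if (anyNA(tab))
    stop(sprintf("parse error in %s: malformed row at line %d",
                 path, which(!complete.cases(tab))[1]), call. = FALSE)
  cov <- tab$meth + tab$unmeth
  recomputed <- ifelse(cov > 0, tab$meth / cov, NA_real_)
  mism <- which(cov > 0 & abs(recomputed - tab$ratio) > 0.01)
  if (length(mism))
    stop(sprintf(
      "validation error in %s line %d: ratio %.4g disagrees with %d/%d",
      path, mism[1], tab$ratio[mism[1]], tab$meth[mism[1]], cov[mism[1]]),
      call. = FALSE)
  if (is.unsorted(order(tab$chrom, tab$start)) ||
      any(diff(order(tab$chrom, tab$start)) != 1L))
    warning(sprintf("%s: input not sorted; sorting", path))
  ratio <- matrix(recomputed, ncol = 1, dimnames = list(NULL, sample_id))
  coverage <- matrix(as.integer(cov), ncol = 1,
                     dimnames = list(NULL, sample_id))
  meth_matrix(tab[, c("chrom", "start", "end")], ratio, coverage)
}

#' Merge single-sample methylation matrices over the union of sites
#'
#' Entries where a sample lacks a site are missing (coverage 0, ratio NA).
#' The result is order-independent in its inputs.
#'
#' @param mats list of \code{\link{meth_matrix}} objects.
#' @return A merged \code{\link{meth_matrix}}.
#' @export
merge_samples <- function(mats) {
  stopifnot(length(mats) >= 1L, all(vapply(mats, inherits, TRUE,
                                           "meth_matrix")))
  ids <- unlist(lapply(mats, function(m) m$samples))
  if (anyDuplicated(ids))
    stop("duplicate sample id: ", ids[duplicated(ids)][1])
  if (length(mats) == 1L) return(mats[[1]])
  keys <- lapply(mats, function(m) paste0(m$sites$chrom, ":", m$sites$start))
  all_sites <- unique(do.call(rbind, lapply(mats, `[[`, "sites")))
  o <- order(all_sites$chrom, all_sites$start)
  all_sites <- all_sites[o, , drop = FALSE]
  rownames(all_sites) <- NULL
  ukey <- paste0(all_sites$chrom, ":", all_sites$start)
  n <- nrow(all_sites)
  ratio <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
  coverage <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  for (i in seq_along(mats)) {
    idx <- match(keys[[i]], ukey)
    for (s in mats[[i]]$samples) {
      ratio[idx, s] <- mats[[i]]$ratio[, s]
      coverage[idx, s] <- mats[[i]]$coverage[, s]
    }
  }
  meth_matrix(all_sites, ratio, coverage)
}

# closed annotation vocabulary
ANNOTATION_CATEGORIES <- c("gene_body", "promoter", "tss", "enhancer",
                           "cpg_island", "other")

#' Read categorized genomic annotations from BED4+
#'
#' The BED name field must encode \code{"category:gene"} (gene optional).
#' Categories outside the closed vocabulary (gene_body, promoter, tss,
#' enhancer, cpg_island, other) are mapped to \code{other} with a warning.
#'
#' @param path BED file path (optionally .gz).
#' @return A \code{GRanges} with metadata columns \code{category},
#'   \code{gene}, \code{name}.
#' @export
read_annotations <- function(path) {
  tab <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) return(NULL)
      stop(e)
    })
  if (is.null(tab)) {
    return(GenomicRanges::GRanges(category = character(0),
                                  gene = character(0), name = character(0)))
  }
  if (ncol(tab) < 4) stop("BED4+ required (need a name field)")
  names(tab)[1:4] <- c("chrom", "start", "end", "name")
  if (any(tab$start >= tab$end))
    stop("annotation with start >= end at line ",
         which(tab$start >= tab$end)[1])
  parts <- strsplit(tab$name, ":", fixed = TRUE)
  category <- vapply(parts, `[`, "", 1)
  gene <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                 "")
  unknown <- !(category %in% ANNOTATION_CATEGORIES)
  if (any(unknown)) {
    warning(sprintf("%d annotation(s) with unknown category mapped to 'other'",
                    sum(unknown)))
    category[unknown] <- "other"
  }
  GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start + 1L, end = tab$end),
    category = category, gene = gene, name = tab$name)
}

# Convert a 0-based half-open data.frame (chrom/start/end) to GRanges.
df_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

# Put two GRanges on the union of their seqlevels so pairwise overlap and
# distance operations do not warn about disjoint chromosome sets.
align_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a, b)
}

#' Read a UCSC chain file
#'
#' Chain header fields: \code{chain score tName tSize tStrand tStart tEnd
#' qName qSize qStrand qStart qEnd id}; the \code{t} side is the source
#' genome (lifted from), the \code{q} side the target. Block arithmetic is
#' validated against the header spans.
#'
#' @param path chain file path (optionally .gz).
#' @return An object of class \code{chain_map}: a list of chains, each with
#'   header fields and a block table.
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr_idx <- grep("^chain\\b", lines)
  chains <- vector("list", length(hdr_idx))
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (i in seq_along(hdr_idx)) {
    h <- strsplit(trimws(lines[hdr_idx[i]]), "\\s+")[[1]]
    if (length(h) < 13) stop("malformed chain header: ", lines[hdr_idx[i]])
    hd <- list(score = as.numeric(h[2]),
               s_chrom = h[3], s_size = as.integer(h[4]), s_strand = h[5],
               s_start = as.integer(h[6]), s_end = as.integer(h[7]),
               t_chrom = h[8], t_size = as.integer(h[9]), t_strand = h[10],
               t_start = as.integer(h[11]), t_end = as.integer(h[12]),
               id = h[13])
    if (!hd$s_strand %in% c("+", "-") || !hd$t_strand %in% c("+", "-"))
      stop("chain ", hd$id, ": invalid strand")
    body <- lines[seq(hdr_idx[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[!grepl("^chain\\b", body)]
    blk <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                                 function(x) as.integer(x[1:3])))
    blk <- as.data.frame(blk)
    names(blk) <- c("size", "ds", "dt")
    # final line has only the size
    blk$ds[nrow(blk)] <- 0L
    blk$dt[nrow(blk)] <- 0L
    if (any(blk < 0, na.rm = TRUE) || anyNA(blk$size))
      stop("chain ", hd$id, ": negative or missing block fields")
    if (sum(blk$size + blk$ds) != hd$s_end - hd$s_start ||
        sum(blk$size + blk$dt) != hd$t_end - hd$t_start)
      stop(sprintf("chain %s: block sums do not match header spans", hd$id))
    # absolute (strand-local) offsets of aligned blocks
    s_off <- hd$s_start + cumsum(c(0L, head(blk$size + blk$ds, -1L)))
    t_off <- hd$t_start + cumsum(c(0L, head(blk$size + blk$dt, -1L)))
    hd$blocks <- data.frame(size = blk$size, s_start = s_off, t_start = t_off)
    chains[[i]] <- hd
  }
  structure(chains, class = "chain_map")
}

#' @export
print.chain_map <- function(x, ...) {
  cat(sprintf("chain_map: %d chain(s)\n", length(x)))
  invisible(x)
}

#' Write DMR records to BED or TSV
#'
#' BED output is 0-based half-open with 6 columns: chrom, start, end, region
#' id, score = round(1000 * |mean difference|) capped at 1000, strand ".".
#' TSV output carries every record field (including per-sample regional
#' means as \code{mean.<sample>} columns) and round-trips bit-exactly
#' through \code{\link{read_regions}}.
#'
#' @param records a \code{dmr_set} (see \code{\link{call_dmrs}}) or a plain
#'   data.frame of regions.
#' @param path output file path.
#' @param format \code{"BED"} or \code{"TSV"}.
#' @return \code{path}, invisibly.
#' @export
write_regions <- function(records, path, format = c("TSV", "BED")) {
  format <- match.arg(toupper(format), c("TSV", "BED"))
  df <- as.data.frame(records)
  if (format == "BED") {
    score <- if ("mean_diff" %in% names(df) && nrow(df))
      pmin(1000L, as.integer(round(1000 * abs(df$mean_diff)))) else
        rep(0L, nrow(df))
    bed <- data.frame(df$chrom, df$start, df$end,
                      if ("id" %in% names(df)) df$id else
                        paste0("dmr_", seq_len(nrow(df))),
                      score, rep(".", nrow(df)))
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
  }
  invisible(path)
}

#' Read DMR records from a TSV written by \code{\link{write_regions}}
#'
#' @param path TSV path.
#' @return data.frame of regions.
#' @export
read_regions <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read sample metadata
#'
#' TSV with header and columns \code{sample}, \code{group}, \code{age},
#' \code{sex}. Ages must be positive so that log(age) is finite.
#'
#' @param path TSV path.
#' @return data.frame of metadata.
#' @export
read_metadata <- function(path) {
  md <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  validate_metadata(md)
  md
}

validate_metadata <- function(md) {
  stopifnot(all(c("sample", "group", "age", "sex") %in% names(md)))
  if (anyDuplicated(md$sample)) stop("duplicate sample in metadata")
  if (any(md$age <= 0)) stop("ages must be > 0 (log(age) must be finite)")
  if (!all(md$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  invisible(md)
}
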