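# ---------------------------------------------------------------------------
# Chain-file liftover and cross-genome DMR correspondence. Intervals are
# mapped base-wise through the aligned blocks of the best-scoring
# overlapping chain; correspondence between sets is scored as direct
# (>= 1 bp shared) and proximal (edge distance <= k, default 10 kb).
# ---------------------------------------------------------------------------

#' Map one interval through a chain map
#'
#' Bases are mapped through the aligned blocks of the best-scoring chain
#' overlapping the interval on the source genome. The target interval is
#' the span of mapped bases; minus-strand chains yield correctly reversed
#' target coordinates. Failure modes are statuses, never errors:
#' \code{unmapped} (no base maps), \code{split} (the best chain maps too
#' little and another chain maps part of the interval), \code{low_ratio}
#' (mapped fraction below \code{min_map_ratio}).
#'
#' @param chain_map a \code{\link{read_chain}} result.
#' @param chrom,start,end source interval (0-based half-open).
#' @param min_map_ratio minimum mapped-base fraction for status
#'   \code{mapped} (default 0.5).
#' @return list: status, chrom/start/end of the target interval (NA unless
#'   usable), mapped_fraction.
#' @export
liftover_interval <- function(chain_map, chrom, start, end,
                              min_map_ratio = 0.5) {
  stopifnot(end > start)
  fail <- function(status, frac = 0)
    list(status = status, chrom = NA_character_, start = NA_integer_,
         end = NA_integer_, mapped_fraction = frac)
  cand <- Filter(function(ch) ch$s_chrom == chrom &&
                   ch$s_start < end && ch$s_end > start, chain_map)
  if (!length(cand)) return(fail("unmapped"))
  cand <- cand[order(vapply(cand, `[[`, 0, "score"), decreasing = TRUE)]
  map_through <- function(ch) {
    b <- ch$blocks
    a <- pmax(b$s_start, start)
    z <- pmin(b$s_start + b$size, end)
    sel <- which(z > a)
    if (!length(sel)) return(NULL)
    toff <- b$t_start[sel] + (a[sel] - b$s_start[sel])
    tlen <- z[sel] - a[sel]
    # strand-local coordinates of mapped pieces on the target genome
    lo <- min(toff)
    hi <- max(toff + tlen)
    if (ch$t_strand == "-") {
      tmp <- ch$t_size - hi
      hi <- ch$t_size - lo
      lo <- tmp
    }
    list(chrom = ch$t_chrom, start = lo, end = hi, mapped = sum(tlen))
  }
  best <- map_through(cand[[1]])
  width <- end - start
  others_map <- length(cand) > 1 &&
    any(vapply(cand[-1], function(ch) !is.null(map_through(ch)), TRUE))
  if (is.null(best)) {
    if (others_map) {
      # best-scoring chain contributes nothing; fall through to the next
      cand2 <- Filter(function(ch) !is.null(map_through(ch)), cand)
      best <- map_through(cand2[[1]])
      others_map <- length(cand2) > 1
    } else {
      return(fail("unmapped"))
    }
  }
  frac <- best$mapped / width
  if (frac >= min_map_ratio)
    return(list(status = "mapped", chrom = best$chrom,
                start = as.integer(best$start), end = as.integer(best$end),
                mapped_fraction = frac))
  if (others_map) return(fail("split", frac))
  fail("low_ratio", frac)
}

#' Lift a table of intervals through a chain map
#'
#' @param chain_map a \code{\link{read_chain}} result.
#' @param regions data.frame with chrom, start, end (0-based half-open).
#' @param min_map_ratio see \code{\link{liftover_interval}}.
#' @return data.frame: source coordinates, status, target coordinates,
#'   mapped_fraction.
#' @export
liftover_regions <- function(chain_map, regions, min_map_ratio = 0.5) {
  regions <- as.data.frame(regions)
  res <- lapply(seq_len(nrow(regions)), function(i)
    liftover_interval(chain_map, regions$chrom[i], regions$start[i],
                      regions$end[i], min_map_ratio))
  data.frame(chrom = regions$chrom, start = regions$start,
             end = regions$end,
             status = vapply(res, `[[`, "", "status"),
             target_chrom = vapply(res, `[[`, "", "chrom"),
             target_start = vapply(res, function(r)
               as.integer(r$start), 0L),
             target_end = vapply(res, function(r) as.integer(r$end), 0L),
             mapped_fraction = vapply(res, `[[`, 0, "mapped_fraction"),
             stringsAsFactors = FALSE)
}

#' Compare two DMR sets, optionally across genomes
#'
#' With a chain, set A is lifted to B's genome first (split and low-ratio
#' maps count as unmapped). Direct correspondence requires at least 1 bp of
#' shared sequence; proximal correspondence requires an edge-to-edge
#' distance of at most \code{k} (overlap counts as distance 0). Percentages
#' are over the full size of A, unmapped intervals included.
#'
#' @param dmrsA,dmrsB DMR sets or region data.frames.
#' @param chain optional \code{chain_map} mapping A's genome to B's.
#' @param k proximity radius in bp (default 10000).
#' @param min_map_ratio passed to the liftover.
#' @return list of class \code{set_comparison}: nA, nB, direct count and
#'   percent, within-k count and percent, unmapped count.
#' @export
compare_dmr_sets <- function(dmrsA, dmrsB, chain = NULL, k = 10000,
                             min_map_ratio = 0.5) {
  a <- as.data.frame(dmrsA)[, c("chrom", "start", "end")]
  b <- as.data.frame(dmrsB)[, c("chrom", "start", "end")]
  nA <- nrow(a)
  nB <- nrow(b)
  unmapped <- 0L
  if (!is.null(chain)) {
    if (nA > 0) {
      schroms <- unique(vapply(chain, `[[`, "", "s_chrom"))
      if (!length(intersect(schroms, unique(a$chrom))))
        stop("chain source genome shares no chromosome with set A")
      lifted <- liftover_regions(chain, a, min_map_ratio)
      ok <- lifted$status == "mapped"
      unmapped <- sum(!ok)
      a <- data.frame(chrom = lifted$target_chrom[ok],
                      start = lifted$target_start[ok],
                      end = lifted$target_end[ok])
    }
  }
  direct <- 0L
  within_k <- 0L
  if (nrow(a) && nrow(b)) {
    al <- align_seqlevels(df_to_gr(a), df_to_gr(b))
    ga <- al[[1]]
    gb <- al[[2]]
    direct <- sum(GenomicRanges::countOverlaps(ga, gb, minoverlap = 1L) > 0)
    dtn <- GenomicRanges::distanceToNearest(ga, gb, ignore.strand = TRUE)
    d <- rep(Inf, nrow(a))
    d[S4Vectors::queryHits(dtn)] <- S4Vectors::mcols(dtn)$distance
    within_k <- sum(d <= k)
  }
  structure(list(nA = nA, nB = nB, direct = direct,
                 direct_pct = if (nA) 100 * direct / nA else NA_real_,
                 within_k = within_k,
                 within_k_pct = if (nA) 100 * within_k / nA else NA_real_,
                 k = k, unmapped = unmapped),
            class = "set_comparison")
}

#' @export
print.set_comparison <- function(x, ...) {
  cat(sprintf(
    "set_comparison: nA=%d nB=%d direct=%d (%.2f%%) within %d bp=%d (%.2f%%) unmapped=%d\n",
    x$nA, x$nB, x$direct, x$direct_pct, x$k, x$within_k, x$within_k_pct,
    x$unmapped))
  invisible(x)
}

#' Bidirectional cross-genome DMR comparison
#'
#' Lifts A to B's genome and B to A's genome, comparing each direction.
#' Asymmetry between the directions is expected and reported, not
#' reconciled.
#'
#' @param dmrsA,dmrsB DMR sets on their own genomes.
#' @param chain_ab chain mapping A's genome to B's.
#' @param chain_ba chain mapping B's genome to A's.
#' @param k proximity radius in bp.
#' @return list with \code{a_to_b} and \code{b_to_a} set comparisons.
#' @export
bidirectional_comparison <- function(dmrsA, dmrsB, chain_ab, chain_ba,
                                     k = 10000) {
  list(a_to_b = compare_dmr_sets(dmrsA, dmrsB, chain = chain_ab, k = k),
       b_to_a = compare_dmr_sets(dmrsB, dmrsA, chain = chain_ba, k = k))
}
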