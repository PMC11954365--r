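# Interval algebra on 0-based half-open coordinates. These primitives define
# the overlap semantics used by every downstream module: the reciprocal-style
# overlap fraction is anchored on the shorter interval, and merging takes the
# convex hull of a cluster.

#' Overlap fraction between two intervals
#'
#' Returns overlap length divided by the length of the *shorter* interval, a
#' symmetric quantity in [0, 1]. Intervals on different chromosomes overlap
#' by 0. The fraction is 1 exactly when one interval contains the other.
#'
#' @param a,b data.frames (or one-row lists) with chrom, start, end; vectors
#'   are recycled row-wise when lengths match
#' @return numeric vector of fractions in [0, 1]
#' @export
#' @examples
#' a <- data.frame(chrom = "chr1", start = 100, end = 200)
#' b <- data.frame(chrom = "chr1", start = 150, end = 250)
#' overlap_fraction(a, b)  # 0.5
overlap_fraction <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  check_intervals(a, "interval a"); check_intervals(b, "interval b")
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  shorter <- pmin(a$end - a$start, b$end - b$start)
  out <- ov / shorter
  out[as.character(a$chrom) != as.character(b$chrom)] <- 0
  out
}

#' Merge a cluster of intervals into their convex hull
#'
#' @param intervals data.frame of intervals on a single chromosome
#' @return one-row data.frame `[min(start), max(end))`
#' @export
merge_cluster <- function(intervals) {
  intervals <- as.data.frame(intervals)
  if (nrow(intervals) == 0) stop("merge_cluster: empty input", call. = FALSE)
  check_intervals(intervals, "interval")
  if (length(unique(as.character(intervals$chrom))) > 1) {
    stop("merge_cluster: intervals span multiple chromosomes", call. = FALSE)
  }
  data.frame(
    chrom = intervals$chrom[1],
    start = min(intervals$start),
    end = max(intervals$end),
    stringsAsFactors = FALSE
  )
}

# All pairs of rows (i < j) whose overlap fraction meets `min_overlap`.
# Uses a GRanges overlap query; returns a 2-column index matrix.
overlap_pairs <- function(df, min_overlap) {
  gr <- intervals_to_granges(df)
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  keep <- q < s
  q <- q[keep]; s <- s[keep]
  if (length(q) == 0) return(matrix(integer(), ncol = 2))
  frac <- overlap_fraction(df[q, c("chrom", "start", "end")],
                           df[s, c("chrom", "start", "end")])
  cbind(q[frac >= min_overlap], s[frac >= min_overlap])
}
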