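# Internal helpers shared across modules.

#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
#' @importFrom stats rpois rgamma rnorm rlnorm runif p.adjust phyper pt quantile setNames
#' @importFrom utils read.table write.table head
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Convert a 0-based half-open interval table to GRanges
#'
#' All on-disk coordinates in this package are BED-style 0-based half-open;
#' GRanges is 1-based closed, so start shifts by +1 and end is kept.
#' @param df data.frame with columns chrom, start, end (and optionally strand)
#' @param genome optional named vector of chromosome lengths used as seqlengths
#' @param levels optional explicit seqlevels (e.g. the union of two tables'
#'   chromosomes, so cross-object overlap queries share a sequence universe)
#' @return a GRanges of the same length
#' @keywords internal
intervals_to_granges <- function(df, genome = NULL, levels = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  if (is.null(levels)) {
    levels <- if (is.null(genome)) unique(as.character(df$chrom)) else names(genome)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(as.character(df$chrom), levels = levels),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  if (!is.null(genome)) GenomeInfoDb::seqlengths(gr) <- genome[GenomeInfoDb::seqlevels(gr)]
  gr
}

# GRanges back to 0-based half-open data.frame.
granges_to_intervals <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Midpoint of 0-based half-open intervals (a 0-based base position).
interval_midpoint <- function(start, end) {
  as.integer(floor((as.numeric(start) + as.numeric(end)) / 2))
}

# 1-bp GRanges at interval midpoints.
midpoint_granges <- function(df, genome = NULL, levels = NULL) {
  mid <- interval_midpoint(df$start, df$end)
  intervals_to_granges(
    data.frame(chrom = df$chrom, start = mid, end = mid + 1L),
    genome = genome, levels = levels
  )
}

# Validate a peak/interval data.frame against the coordinate invariants.
check_intervals <- function(df, what = "interval") {
  if (!is.data.frame(df) || !all(c("chrom", "start", "end") %in% names(df))) {
    stop(what, " table must have columns chrom, start, end", call. = FALSE)
  }
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom) | !nzchar(as.character(df$chrom)))) {
    stop(what, ": chromosome names must be non-empty", call. = FALSE)
  }
  if (any(df$start < 0)) stop(what, ": start must be >= 0", call. = FALSE)
  if (any(df$end <= df$start)) stop(what, ": end must be > start", call. = FALSE)
  invisible(df)
}

# Intervals must lie within their chromosome; names are matched strictly
# ("chr1" and "1" are different chromosomes by design).
check_within_genome <- function(df, genome, what = "interval") {
  if (nrow(df) == 0) return(invisible(df))
  unknown <- setdiff(unique(as.character(df$chrom)), names(genome))
  if (length(unknown) > 0) {
    stop(what, ": chromosome(s) not in genome (strict name match): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(df$end > genome[as.character(df$chrom)])) {
    stop(what, ": interval extends past chromosome end", call. = FALSE)
  }
  invisible(df)
}

# Disjoint-set union-find over n elements; `pairs` is a 2-column matrix of
# indices to link. Returns cluster id per element.
union_find <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[b] <- a
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Run `expr` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
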