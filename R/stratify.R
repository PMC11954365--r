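# Stratify differential ATAC peaks by ChIP binding overlap and compute
# paired fixed-width coverage matrices around peak centers (the numeric
# substrate of binding-site heatmaps and profiles).

#' Partition differential ATAC peaks by ChIP-peak overlap
#'
#' An ATAC peak is "bound" when it overlaps any ChIP peak by at least
#' `min_bp` base pairs (default 1). The six cells
#' {bound, unbound} x {up, down, same} partition the input.
#'
#' @param atac_peaks data.frame of peaks with a `class` column in
#'   up/down/same
#' @param chip_peaks data.frame of (consensus, non-overlapping) ChIP peaks
#' @param min_bp minimum overlap in bp to count as bound
#' @return list with `cells` (named list of the six peak subsets), `counts`
#'   (2 x 3 matrix) and the input with a `bound` column
#' @export
stratify_by_binding <- function(atac_peaks, chip_peaks, min_bp = 1) {
  check_intervals(atac_peaks, "ATAC peak")
  check_intervals(chip_peaks, "ChIP peak")
  if (!("class" %in% names(atac_peaks)) ||
      !all(atac_peaks$class %in% c("up", "down", "same"))) {
    stop("atac_peaks need a class column in up/down/same", call. = FALSE)
  }
  if (nrow(chip_peaks) > 0) {
    lv <- union(unique(as.character(atac_peaks$chrom)),
                unique(as.character(chip_peaks$chrom)))
    chip_gr <- intervals_to_granges(chip_peaks, levels = lv)
    if (!IRanges::isDisjoint(chip_gr)) {
      stop("chip_peaks must be non-overlapping (consensus)", call. = FALSE)
    }
    bound <- IRanges::overlapsAny(intervals_to_granges(atac_peaks, levels = lv),
                                  chip_gr,
                                  minoverlap = as.integer(min_bp),
                                  ignore.strand = TRUE)
  } else {
    bound <- rep(FALSE, nrow(atac_peaks))
  }
  atac_peaks$bound <- bound
  cells <- list()
  counts <- matrix(0L, nrow = 2, ncol = 3,
                   dimnames = list(c("bound", "unbound"), c("up", "down", "same")))
  for (b in c(TRUE, FALSE)) {
    for (cl in c("up", "down", "same")) {
      key <- paste0(if (b) "bound" else "unbound", "_", cl)
      cells[[key]] <- atac_peaks[atac_peaks$bound == b & atac_peaks$class == cl, ,
                                 drop = FALSE]
      counts[if (b) "bound" else "unbound", cl] <- nrow(cells[[key]])
    }
  }
  list(cells = cells, counts = counts, peaks = atac_peaks)
}

#' Fixed-width regions around peak centers
#'
#' Each region is `[center - flank, center + flank)` with
#' center = floor((start + end) / 2). Regions that would extend past a
#' chromosome end (or below 0) are dropped with a warning so all rows of a
#' coverage matrix are commensurate.
#'
#' @param peaks data.frame with chrom, start, end (and optionally name)
#' @param flank half-width in bp (default 1500)
#' @param genome optional named vector of chromosome lengths; when given,
#'   regions running past the chromosome end are dropped too
#' @return data.frame of regions (chrom, start, end, name, source_name) with
#'   attribute `flank`
#' @export
make_regions <- function(peaks, flank = 1500, genome = NULL) {
  if (flank <= 0) stop("flank must be > 0", call. = FALSE)
  check_intervals(peaks, "peak")
  center <- interval_midpoint(peaks$start, peaks$end)
  start <- center - as.integer(flank)
  end <- center + as.integer(flank)
  keep <- start >= 0
  if (!is.null(genome)) {
    unknown <- setdiff(unique(as.character(peaks$chrom)), names(genome))
    if (length(unknown)) {
      stop("make_regions: chromosome(s) not in genome: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    keep <- keep & end <= genome[as.character(peaks$chrom)]
  }
  dropped <- sum(!keep)
  if (dropped > 0) {
    warning(dropped, " region(s) dropped: would extend past chromosome bounds")
  }
  out <- data.frame(
    chrom = peaks$chrom[keep],
    start = start[keep],
    end = end[keep],
    name = sprintf("region_%05d", seq_len(sum(keep))),
    source_name = (peaks$name %||% rep(NA_character_, nrow(peaks)))[keep],
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "flank") <- flank
  out
}

#' Binned fragment coverage over fixed-width regions
#'
#' value(r, b) is the number of fragments whose midpoint falls in bin b of
#' region r (bins of `bin_size` bp, left to right). With
#' `norm = "per_million"` counts are scaled by 1e6 / total fragments in the
#' sample. Regions may overlap; a fragment is counted in every region that
#' contains its midpoint.
#'
#' @param fragments data.frame with chrom, start, end
#' @param regions output of [make_regions()] (all rows the same width)
#' @param bin_size bp per bin; must divide the region width exactly
#' @param norm "raw" or "per_million"
#' @return numeric matrix, regions x bins, rownames from region names;
#'   attributes `bin_size` and `norm`
#' @export
coverage_matrix <- function(fragments, regions, bin_size = 50,
                            norm = c("raw", "per_million")) {
  norm <- match.arg(norm)
  check_intervals(regions, "region")
  check_intervals(fragments, "fragment")
  width <- unique(regions$end - regions$start)
  if (length(width) > 1) stop("regions must all have the same width", call. = FALSE)
  if (length(width) == 0) width <- 0L
  if (width > 0 && width %% bin_size != 0) {
    stop("bin_size must divide the region width exactly", call. = FALSE)
  }
  n_bins <- if (width > 0) width %/% bin_size else 0L
  m <- matrix(0, nrow = nrow(regions), ncol = n_bins,
              dimnames = list(regions$name, NULL))
  if (nrow(regions) > 0 && nrow(fragments) > 0 && n_bins > 0) {
    lv <- union(unique(as.character(fragments$chrom)),
                unique(as.character(regions$chrom)))
    mids <- interval_midpoint(fragments$start, fragments$end)
    mid_gr <- intervals_to_granges(
      data.frame(chrom = fragments$chrom, start = mids, end = mids + 1L),
      levels = lv
    )
    reg_gr <- intervals_to_granges(regions, levels = lv)
    hits <- GenomicRanges::findOverlaps(mid_gr, reg_gr, ignore.strand = TRUE)
    if (length(hits) > 0) {
      fi <- S4Vectors::queryHits(hits)
      ri <- S4Vectors::subjectHits(hits)
      bin <- (mids[fi] - regions$start[ri]) %/% bin_size + 1L
      flat <- (bin - 1L) * nrow(regions) + ri  # column-major cell index
      m[] <- m + tabulate(flat, nbins = nrow(regions) * n_bins)
    }
  }
  if (norm == "per_million" && nrow(fragments) > 0) {
    m <- m * 1e6 / nrow(fragments)
  }
  attr(m, "bin_size") <- bin_size
  attr(m, "norm") <- norm
  m
}

#' Paired coverage matrices over one shared region list
#'
#' Computes [coverage_matrix()] for two fragment sets (e.g. WT and KO) over
#' exactly the same regions, guaranteeing identical region lists and shapes.
#'
#' @param fragments_a,fragments_b fragment tables
#' @param regions shared regions (typically derived from KO peaks)
#' @inheritParams coverage_matrix
#' @return named list of two matrices (`a`, `b`)
#' @export
coverage_pair <- function(fragments_a, fragments_b, regions, bin_size = 50,
                          norm = c("raw", "per_million")) {
  norm <- match.arg(norm)
  list(
    a = coverage_matrix(fragments_a, regions, bin_size = bin_size, norm = norm),
    b = coverage_matrix(fragments_b, regions, bin_size = bin_size, norm = norm)
  )
}

#' Mean per-bin profile of a coverage matrix
#'
#' @param rm matrix from [coverage_matrix()] (>= 1 region)
#' @return numeric vector of column means, length = number of bins
#' @export
region_profile <- function(rm) {
  if (!is.matrix(rm) || nrow(rm) == 0) {
    stop("region_profile: empty matrix", call. = FALSE)
  }
  colMeans(rm)
}
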