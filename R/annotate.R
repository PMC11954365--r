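# Genomic feature classification of peaks. Every base of the genome gets
# exactly one class under the precedence TSS > 5'UTR > exon > intron >
# intergenic; a peak's class is the class of its midpoint base. The
# region-size-normalized proportion compares where peaks fall against how
# much of the genome each class occupies.

FEATURE_CLASSES <- c("TSS", "5UTR", "exon", "intron", "intergenic")

#' Build a disjoint feature-class map of the genome
#'
#' Labels every base with the highest-precedence overlapping feature:
#' TSS window (tss +/- `tss_halfwidth`, clipped to the chromosome) beats
#' 5' UTR beats exon beats intron (gene span minus exons) beats intergenic.
#' Class sizes tile the genome exactly.
#'
#' @param annotation a [gene_annotation()]
#' @param genome named vector of chromosome lengths
#' @param tss_halfwidth half-width of the TSS window in bp (default 500)
#' @return list with per-class GRanges (`class_regions`), per-class bp
#'   (`class_sizes`) and the genome; class `feature_map`
#' @export
build_feature_map <- function(annotation, genome, tss_halfwidth = 500) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (tss_halfwidth <= 0) stop("tss_halfwidth must be > 0", call. = FALSE)
  genes <- annotation$genes
  if (nrow(genes)) check_within_genome(genes, genome, "gene")

  genome_gr <- GenomicRanges::GRanges(
    seqnames = names(genome),
    ranges = IRanges::IRanges(start = 1L, end = unname(genome))
  )
  GenomeInfoDb::seqlengths(genome_gr) <- genome

  to_gr <- function(df) {
    if (is.null(df) || nrow(df) == 0) {
      gr <- GenomicRanges::GRanges(seqlengths = genome)
      return(gr)
    }
    GenomicRanges::reduce(intervals_to_granges(df[, c("chrom", "start", "end")], genome),
                          ignore.strand = TRUE)
  }

  if (nrow(genes)) {
    tss_df <- data.frame(
      chrom = genes$chrom,
      start = pmax(0L, genes$tss - as.integer(tss_halfwidth)),
      end = pmin(unname(genome[as.character(genes$chrom)]),
                 genes$tss + as.integer(tss_halfwidth)),
      stringsAsFactors = FALSE
    )
  } else {
    tss_df <- NULL
  }
  tss_gr <- to_gr(tss_df)
  utr_gr <- to_gr(annotation$utr5)
  exon_gr <- to_gr(annotation$exons)
  span_gr <- to_gr(genes)
  intron_gr <- GenomicRanges::setdiff(span_gr, exon_gr, ignore.strand = TRUE)

  # apply precedence by subtracting everything of higher rank
  regions <- list()
  regions$TSS <- tss_gr
  taken <- tss_gr
  for (pair in list(list("5UTR", utr_gr), list("exon", exon_gr),
                    list("intron", intron_gr))) {
    r <- GenomicRanges::setdiff(pair[[2]], taken, ignore.strand = TRUE)
    regions[[pair[[1]]]] <- r
    taken <- GenomicRanges::reduce(c(taken, r), ignore.strand = TRUE)
  }
  regions$intergenic <- GenomicRanges::setdiff(genome_gr, taken, ignore.strand = TRUE)

  sizes <- vapply(regions, function(r) sum(as.numeric(GenomicRanges::width(r))), 0)
  structure(list(class_regions = regions, class_sizes = sizes, genome = genome),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat("feature_map over", sum(as.numeric(x$genome)), "bp:\n")
  print(round(x$class_sizes))
  invisible(x)
}

#' Feature class of each peak's midpoint
#'
#' @param peaks data.frame with chrom, start, end
#' @param fmap a `feature_map`
#' @return character vector of classes, one per peak
#' @export
peak_feature_class <- function(peaks, fmap) {
  stopifnot(inherits(fmap, "feature_map"))
  check_intervals(peaks, "peak")
  check_within_genome(peaks, fmap$genome, "peak")
  if (nrow(peaks) == 0) return(character())
  mids <- midpoint_granges(peaks, fmap$genome)
  cls <- rep(NA_character_, nrow(peaks))
  for (cn in FEATURE_CLASSES) {
    hit <- IRanges::overlapsAny(mids, fmap$class_regions[[cn]],
                                      ignore.strand = TRUE)
    cls[is.na(cls) & hit] <- cn
  }
  cls
}

#' Region-size-normalized peak proportions per feature class
#'
#' For class c: (peaks with midpoint in c / all peaks) divided by
#' (bp of c / genome bp). A value of 1 means the class holds exactly its
#' genomic share of peaks.
#'
#' @param peaks data.frame with chrom, start, end (>= 1 peak)
#' @param fmap a `feature_map`
#' @return data.frame: class, n_peaks, prop_peaks, class_size, prop_size,
#'   enrichment
#' @export
region_proportion_enrichment <- function(peaks, fmap) {
  if (nrow(peaks) == 0) stop("need >= 1 peak", call. = FALSE)
  cls <- peak_feature_class(peaks, fmap)
  n <- vapply(FEATURE_CLASSES, function(cn) sum(cls == cn), 0)
  prop_peaks <- n / nrow(peaks)
  prop_size <- fmap$class_sizes[FEATURE_CLASSES] / sum(as.numeric(fmap$genome))
  data.frame(
    class = FEATURE_CLASSES,
    n_peaks = as.integer(n),
    prop_peaks = prop_peaks,
    class_size = unname(fmap$class_sizes[FEATURE_CLASSES]),
    prop_size = unname(prop_size),
    enrichment = ifelse(prop_size > 0, prop_peaks / prop_size, NA_real_),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Assign peaks to genes
#'
#' A peak is assigned to the gene with the nearest TSS within
#' `max_tss_distance` bp of the peak midpoint (ties broken by
#' lexicographically smaller gene_id); failing that, to a gene whose span
#' contains the midpoint (same tie-break); otherwise it stays unassigned.
#' The reported TSS distance is strand-aware: positive means the midpoint
#' lies downstream of the TSS.
#'
#' @param peaks data.frame with chrom, start, end (and optionally name)
#' @param annotation a [gene_annotation()]
#' @param max_tss_distance assignment radius in bp (default 5000)
#' @return data.frame: peak name/coords, gene_id (NA when unassigned),
#'   distance_to_tss, assigned_by ("tss", "span" or "none")
#' @export
assign_peaks_to_genes <- function(peaks, annotation, max_tss_distance = 5000) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (max_tss_distance <= 0) stop("max_tss_distance must be > 0", call. = FALSE)
  check_intervals(peaks, "peak")
  genes <- annotation$genes
  out <- data.frame(
    name = peaks$name %||% sprintf("peak_%05d", seq_len(nrow(peaks))),
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    gene_id = NA_character_, distance_to_tss = NA_real_,
    assigned_by = "none",
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (nrow(peaks) == 0 || nrow(genes) == 0) return(out)
  mid <- interval_midpoint(peaks$start, peaks$end)

  # order genes so that ties at equal distance resolve to the smaller gene_id
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  for (i in seq_len(nrow(peaks))) {
    same <- genes$chrom == as.character(peaks$chrom[i])
    if (!any(same)) next
    g <- genes[same, , drop = FALSE]
    d <- abs(mid[i] - g$tss)
    j <- which(d == min(d))[1]  # first = smallest gene_id among ties
    if (d[j] <= max_tss_distance) {
      out$gene_id[i] <- g$gene_id[j]
      out$distance_to_tss[i] <- signed_tss_distance(mid[i], g$tss[j], g$strand[j])
      out$assigned_by[i] <- "tss"
      next
    }
    inside <- which(g$start <= mid[i] & mid[i] < g$end)
    if (length(inside)) {
      j <- inside[1]
      out$gene_id[i] <- g$gene_id[j]
      out$distance_to_tss[i] <- signed_tss_distance(mid[i], g$tss[j], g$strand[j])
      out$assigned_by[i] <- "span"
    }
  }
  out
}

signed_tss_distance <- function(mid, tss, strand) {
  if (strand == "-") tss - mid else mid - tss
}
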