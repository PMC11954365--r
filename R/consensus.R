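# Replicate-consensus peak aggregation and the master peak list. A peak is
# kept only when supported by >= 2 replicates under the 50%-of-shorter
# overlap rule; the master list is the any-overlap union across samples.

#' Aggregate per-replicate peak calls into a consensus set
#'
#' Peaks whose pairwise overlap fraction (length of overlap over the shorter
#' peak) meets `min_overlap` are clustered transitively and merged into their
#' convex hull. Clusters supported by a single replicate are discarded.
#' Consensus hulls that still overlap each other are merged again so the
#' returned set is pairwise non-overlapping.
#'
#' @param replicate_peaks data.frame of peaks with a `replicate_id` column
#'   (>= 2 distinct replicates required), or a named list of per-replicate
#'   peak tables
#' @param min_overlap minimum overlap fraction in (0, 1], default 0.5
#' @param sample_id label stored on the result
#' @return data.frame of consensus peaks (chrom, start, end, name, support,
#'   n_peaks) with attributes `sample_id` and `replicates`; class
#'   `consensus_peaks`
#' @export
aggregate_replicates <- function(replicate_peaks, min_overlap = 0.5,
                                 sample_id = NA_character_) {
  if (is.list(replicate_peaks) && !is.data.frame(replicate_peaks)) {
    ids <- names(replicate_peaks) %||% paste0("rep", seq_along(replicate_peaks))
    replicate_peaks <- do.call(rbind, lapply(seq_along(replicate_peaks), function(i) {
      df <- replicate_peaks[[i]]
      df$replicate_id <- ids[i]
      df
    }))
  }
  if (!("replicate_id" %in% names(replicate_peaks))) {
    stop("aggregate_replicates: peaks need a replicate_id column", call. = FALSE)
  }
  check_intervals(replicate_peaks, "peak")
  if (!(min_overlap > 0 && min_overlap <= 1)) {
    stop("min_overlap must be in (0, 1]", call. = FALSE)
  }
  reps <- unique(as.character(replicate_peaks$replicate_id))
  if (length(reps) < 2) {
    stop("consensus undefined: need peaks from >= 2 replicates", call. = FALSE)
  }
  df <- replicate_peaks[order(replicate_peaks$chrom, replicate_peaks$start,
                              replicate_peaks$end), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) == 0) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), support = integer(), n_peaks = integer(),
                      stringsAsFactors = FALSE)
    return(as_consensus(out, sample_id, reps))
  }

  cl <- union_find(nrow(df), overlap_pairs(df, min_overlap))
  hulls <- do.call(rbind, lapply(split(seq_len(nrow(df)), cl), function(idx) {
    support <- length(unique(as.character(df$replicate_id[idx])))
    if (support < 2) return(NULL)
    h <- merge_cluster(df[idx, c("chrom", "start", "end")])
    h$support <- support
    h$n_peaks <- length(idx)
    h
  }))
  if (is.null(hulls) || nrow(hulls) == 0) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), support = integer(), n_peaks = integer(),
                      stringsAsFactors = FALSE)
    return(as_consensus(out, sample_id, reps))
  }

  # Hulls of distinct clusters can still touch; merge any-overlap so the
  # consensus set is pairwise non-overlapping (supports are re-unioned).
  cl2 <- union_find(nrow(hulls), overlap_pairs(hulls, min_overlap = 1e-9))
  out <- do.call(rbind, lapply(split(seq_len(nrow(hulls)), cl2), function(idx) {
    h <- merge_cluster(hulls[idx, c("chrom", "start", "end")])
    h$support <- max(hulls$support[idx])
    h$n_peaks <- sum(hulls$n_peaks[idx])
    h
  }))
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out$name <- sprintf("%s_consensus_%04d", ifelse(is.na(sample_id), "peak", sample_id),
                      seq_len(nrow(out)))
  out <- out[, c("chrom", "start", "end", "name", "support", "n_peaks")]
  as_consensus(out, sample_id, reps)
}

as_consensus <- function(df, sample_id, replicates) {
  attr(df, "sample_id") <- sample_id
  attr(df, "replicates") <- replicates
  class(df) <- c("consensus_peaks", "data.frame")
  df
}

#' Union of consensus peak sets into a master peak list
#'
#' Peaks from different samples that overlap by >= 1 bp are merged
#' transitively; the result is sorted and pairwise non-overlapping, and each
#' master peak records the contributing samples.
#'
#' @param sets list of consensus peak tables (named by sample, or carrying a
#'   `sample_id` attribute)
#' @return data.frame with chrom, start, end, name, samples (comma-separated
#'   contributing sample ids)
#' @export
union_peak_lists <- function(sets) {
  if (!is.list(sets) || is.data.frame(sets)) sets <- list(sets)
  if (length(sets) == 0) stop("union_peak_lists: need >= 1 peak set", call. = FALSE)
  ids <- names(sets)
  if (is.null(ids)) ids <- rep(NA_character_, length(sets))
  all <- do.call(rbind, lapply(seq_along(sets), function(i) {
    df <- as.data.frame(sets[[i]])[, c("chrom", "start", "end"), drop = FALSE]
    if (nrow(df) == 0) return(NULL)
    sid <- ids[i]
    if (is.na(sid) || !nzchar(sid)) sid <- attr(sets[[i]], "sample_id") %||% paste0("set", i)
    if (is.na(sid)) sid <- paste0("set", i)
    df$sample <- sid
    df
  }))
  if (is.null(all) || nrow(all) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), samples = character(), stringsAsFactors = FALSE))
  }
  check_intervals(all, "peak")
  gr <- intervals_to_granges(all)
  merged <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(merged, gr, ignore.strand = TRUE)
  contrib <- vapply(
    split(all$sample[S4Vectors::subjectHits(hits)], S4Vectors::queryHits(hits)),
    function(s) paste(sort(unique(s)), collapse = ","), ""
  )
  out <- granges_to_intervals(merged)
  out$name <- sprintf("master_%05d", seq_len(nrow(out)))
  out$samples <- ""
  out$samples[as.integer(names(contrib))] <- unname(contrib)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count fragments under a master peak list
#'
#' A fragment is assigned to the unique master peak containing its midpoint,
#' so each fragment is counted at most once and column totals never exceed
#' the fragment totals.
#'
#' @param fragments named list of per-sample fragment tables (chrom, start, end)
#' @param master master peak list (pairwise non-overlapping)
#' @return a raw [count_matrix()] with peak widths as feature lengths
#' @export
count_fragments_in_peaks <- function(fragments, master) {
  check_intervals(master, "master peak")
  if (!is.list(fragments) || is.data.frame(fragments)) {
    stop("fragments must be a named list of per-sample tables", call. = FALSE)
  }
  if (is.null(names(fragments)) || any(!nzchar(names(fragments)))) {
    stop("fragment list must be named by sample", call. = FALSE)
  }
  lv <- unique(c(as.character(master$chrom),
                 unlist(lapply(fragments, function(fr) unique(as.character(fr$chrom))))))
  master_gr <- intervals_to_granges(master, levels = lv)
  if (!IRanges::isDisjoint(master_gr)) {
    stop("master peaks must be non-overlapping", call. = FALSE)
  }
  feat <- master$name %||% sprintf("peak_%05d", seq_len(nrow(master)))
  counts <- vapply(fragments, function(fr) {
    check_intervals(fr, "fragment")
    n <- integer(nrow(master))
    if (nrow(fr) > 0) {
      hits <- GenomicRanges::findOverlaps(midpoint_granges(fr, levels = lv), master_gr,
                                          ignore.strand = TRUE)
      tab <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(master))
      n <- as.integer(tab)
    }
    n
  }, integer(nrow(master)))
  counts <- matrix(counts, nrow = nrow(master),
                   dimnames = list(feat, names(fragments)))
  count_matrix(counts, feature_lengths = setNames(master$end - master$start, feat))
}
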