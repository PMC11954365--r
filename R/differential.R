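# Count container, library-size normalization and the tri-class differential
# call (up / down / same by log2 fold change, with an optional Welch-t + BH
# FDR filter for replicated designs).

#' Construct a count matrix
#'
#' @param counts numeric matrix, features x samples, non-negative; dimnames
#'   give feature and sample ids
#' @param feature_lengths named numeric vector of feature lengths in bp
#'   (required for TPM)
#' @param norm_state one of "raw", "CPM", "TPM"
#' @return list with elements counts, feature_lengths, norm_state; class
#'   `count_matrix`
#' @export
count_matrix <- function(counts, feature_lengths = NULL, norm_state = "raw") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("f%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  norm_state <- match.arg(norm_state, c("raw", "CPM", "TPM"))
  if (!is.null(feature_lengths)) {
    if (is.null(names(feature_lengths))) {
      stop("feature_lengths must be named by feature", call. = FALSE)
    }
    missing <- setdiff(rownames(counts), names(feature_lengths))
    if (length(missing)) {
      stop("feature_lengths missing for: ", paste(head(missing, 3), collapse = ", "),
           call. = FALSE)
    }
    feature_lengths <- feature_lengths[rownames(counts)]
    if (any(feature_lengths <= 0)) stop("feature lengths must be > 0", call. = FALSE)
  }
  structure(list(counts = counts, feature_lengths = feature_lengths,
                 norm_state = norm_state),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts), "samples,",
      "norm_state =", x$norm_state, "\n")
  invisible(x)
}

#' Write a count matrix as TSV (feature_id then one column per sample)
#' @param cm a `count_matrix`
#' @param path output path
#' @return invisibly, the path
#' @export
write_counts_tsv <- function(cm, path) {
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Library-size normalization (CPM or TPM)
#'
#' CPM scales each sample to one million counts. TPM first divides by
#' feature length, then scales each sample so the column sums to one
#' million; every TPM column therefore sums to 1e6 exactly (up to floating
#' point).
#'
#' @param cm a raw `count_matrix`
#' @param method "TPM" or "CPM"
#' @return a `count_matrix` with the chosen norm_state
#' @export
normalize_counts <- function(cm, method = c("TPM", "CPM")) {
  stopifnot(inherits(cm, "count_matrix"))
  method <- match.arg(method)
  if (cm$norm_state != "raw") {
    stop("normalize_counts: matrix already normalized (", cm$norm_state, ")",
         call. = FALSE)
  }
  m <- cm$counts
  if (method == "CPM") {
    cs <- colSums(m)
    if (any(cs == 0)) stop("zero column sum; cannot normalize", call. = FALSE)
    out <- sweep(m, 2, cs, "/") * 1e6
  } else {
    if (is.null(cm$feature_lengths)) {
      stop("TPM requires feature_lengths", call. = FALSE)
    }
    rate <- m / cm$feature_lengths
    cs <- colSums(rate)
    if (any(cs == 0)) stop("zero column sum; cannot normalize", call. = FALSE)
    out <- sweep(rate, 2, cs, "/") * 1e6
  }
  count_matrix(out, feature_lengths = cm$feature_lengths, norm_state = method)
}

#' Three-class differential call between two sample groups
#'
#' Computes per-feature log2 fold change of group means on normalized values
#' with a pseudocount, and classifies every feature as "up", "down" or
#' "same". The class boundary is inclusive: |log2FC| >= `lfc_cutoff` is a
#' call. With `use_fdr = TRUE` a Welch t-test on log2(normalized + 1) values
#' is BH-adjusted and calls additionally require q <= `q_max`.
#'
#' @param cm a normalized `count_matrix`
#' @param group_a,group_b disjoint character vectors of sample (column) names;
#'   fold change is b over a (e.g. a = WT, b = KO)
#' @param lfc_cutoff positive log2 fold-change cutoff
#' @param use_fdr apply the FDR filter (needs >= 2 samples per group)
#' @param q_max FDR ceiling when `use_fdr`
#' @param pseudocount added to both group means before the ratio
#' @return data.frame: feature_id, mean_a, mean_b, log2fc, p_value, q_value,
#'   class
#' @export
classify_differential <- function(cm, group_a, group_b, lfc_cutoff = 0.4,
                                  use_fdr = FALSE, q_max = 0.05,
                                  pseudocount = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  if (cm$norm_state == "raw") {
    stop("classify_differential expects a normalized matrix", call. = FALSE)
  }
  if (lfc_cutoff <= 0) stop("lfc_cutoff must be > 0", call. = FALSE)
  if (length(intersect(group_a, group_b))) {
    stop("groups a and b overlap", call. = FALSE)
  }
  missing <- setdiff(c(group_a, group_b), colnames(cm$counts))
  if (length(missing)) {
    stop("unknown sample(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  a <- cm$counts[, group_a, drop = FALSE]
  b <- cm$counts[, group_b, drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  lfc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))

  p <- q <- rep(NA_real_, nrow(a))
  if (use_fdr) {
    if (length(group_a) < 2 || length(group_b) < 2) {
      stop("use_fdr requires >= 2 samples per group", call. = FALSE)
    }
    la <- log2(a + 1); lb <- log2(b + 1)
    na <- ncol(la); nb <- ncol(lb)
    va <- apply(la, 1, stats::var); vb <- apply(lb, 1, stats::var)
    se2 <- va / na + vb / nb
    tstat <- (rowMeans(lb) - rowMeans(la)) / sqrt(se2)
    # Welch-Satterthwaite degrees of freedom
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
    p[se2 == 0] <- 1  # identical values in both groups
    q <- p.adjust(p, method = "BH")
  }

  pass <- if (use_fdr) !is.na(q) & q <= q_max else TRUE
  class <- ifelse(lfc >= lfc_cutoff & pass, "up",
                  ifelse(lfc <= -lfc_cutoff & pass, "down", "same"))
  data.frame(
    feature_id = rownames(cm$counts),
    mean_a = mean_a, mean_b = mean_b, log2fc = lfc,
    p_value = p, q_value = q, class = class,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a differential table as TSV
#' @param diff result of [classify_differential()]
#' @param path output path
#' @return invisibly, the path
#' @export
write_differential_tsv <- function(diff, path) {
  write.table(diff, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fragment-size quality control
#'
#' Histograms fragment lengths in 10-bp bins and reports the fraction of
#' fragments strictly below 100 bp (open-chromatin, sub-nucleosomal cut
#' pattern), the modal size within the mono-nucleosome search window
#' (bin centers >= 120 bp) and whether a strict local maximum exists with a
#' bin center in [160, 260] bp (nucleosome periodicity).
#'
#' @param fragments data.frame with chrom, start, end (>= 100 fragments)
#' @return list: fraction_below_100bp, modal_size, periodicity_flag,
#'   histogram (data.frame of bin centers and counts)
#' @export
fragment_size_qc <- function(fragments) {
  check_intervals(fragments, "fragment")
  sizes <- fragments$end - fragments$start
  if (length(sizes) < 100) {
    stop("fragment_size_qc needs >= 100 fragments", call. = FALSE)
  }
  bin <- floor(sizes / 10) + 1L
  counts <- tabulate(bin, nbins = max(bin))
  centers <- (seq_along(counts) - 1L) * 10 + 5
  frac_short <- mean(sizes < 100)

  nuc <- which(centers >= 120)
  modal_size <- if (length(nuc)) centers[nuc[which.max(counts[nuc])]] else NA_real_

  # strict local maximum with center in [160, 260]
  flag <- FALSE
  for (i in seq_along(counts)) {
    if (centers[i] < 160 || centers[i] > 260) next
    left <- if (i > 1) counts[i - 1] else -Inf
    right <- if (i < length(counts)) counts[i + 1] else -Inf
    if (counts[i] > left && counts[i] > right) { flag <- TRUE; break }
  }
  list(
    fraction_below_100bp = frac_short,
    modal_size = modal_size,
    periodicity_flag = flag,
    histogram = data.frame(center = centers, count = counts)
  )
}
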