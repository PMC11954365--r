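# Readers and writers for the plain-text formats the pipeline consumes:
# BED3-BED6 peaks/fragments, two-column chrom sizes, BED12 gene models,
# counts TSV and GMT gene-set collections. BED coordinates are 0-based
# half-open and are preserved verbatim.

#' Read a BED3-BED6 file into a peak table
#'
#' Columns 1-3 are required (chrom, start, end); optional column 4 is kept as
#' the record name and column 5 as a non-negative score. Column 6 (strand) is
#' carried but ignored by all overlap operations. Records are returned sorted
#' by (chrom, start, end).
#'
#' @param path path to a tab-separated BED file without header
#' @param sample_id sample label attached to every record
#' @param replicate_id replicate label attached to every record
#' @return data.frame with columns chrom, start, end, name, score, strand,
#'   sample_id, replicate_id, support
#' @export
read_bed <- function(path, sample_id = NA_character_, replicate_id = NA_character_) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_peaks(sample_id, replicate_id))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 tab-separated columns",
         call. = FALSE)
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("malformed BED line ", bad[1], ": non-integer coordinates", call. = FALSE)
  inv <- which(end <= start | start < 0)
  if (length(inv)) {
    stop("malformed BED line ", inv[1], ": end <= start or negative start", call. = FALSE)
  }
  get_col <- function(i, default) {
    ifelse(nf >= i, vapply(fields, function(f) if (length(f) >= i) f[i] else default, ""), default)
  }
  score <- suppressWarnings(as.numeric(get_col(5, "0")))
  score[is.na(score)] <- 0
  if (any(score < 0)) stop("BED score must be non-negative", call. = FALSE)
  df <- data.frame(
    chrom = vapply(fields, `[`, "", 1),
    start = start,
    end = end,
    name = get_col(4, NA_character_),
    score = score,
    strand = ifelse(get_col(6, "*") %in% c("+", "-"), get_col(6, "*"), "*"),
    sample_id = sample_id,
    replicate_id = replicate_id,
    support = 1L,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_peaks <- function(sample_id = NA_character_, replicate_id = NA_character_) {
  data.frame(
    chrom = character(), start = integer(), end = integer(),
    name = character(), score = numeric(), strand = character(),
    sample_id = character(), replicate_id = character(), support = integer(),
    stringsAsFactors = FALSE
  )
}

#' Write a peak table as BED
#'
#' Emits BED6 when name/score/strand are present, BED3 otherwise. An optional
#' extra column can carry the replicate support count.
#'
#' @param peaks data.frame with at least chrom, start, end
#' @param path output path
#' @param support write a 7th column with the support count
#' @return invisibly, the path
#' @export
write_bed <- function(peaks, path, support = FALSE) {
  check_intervals(peaks, "peak")
  cols <- data.frame(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = if ("name" %in% names(peaks)) ifelse(is.na(peaks$name), ".", peaks$name) else ".",
    score = if ("score" %in% names(peaks)) peaks$score else 0,
    strand = if ("strand" %in% names(peaks)) ifelse(is.na(peaks$strand), "*", peaks$strand) else "*",
    stringsAsFactors = FALSE
  )
  if (support) cols$support <- if ("support" %in% names(peaks)) peaks$support else 1L
  write.table(cols, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome sizes file
#'
#' @param path TSV with chromosome name and length, no header
#' @return named integer vector of chromosome lengths
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("chrom sizes file needs two columns", call. = FALSE)
  sizes <- as.integer(df[[2]])
  if (any(is.na(sizes) | sizes <= 0)) stop("chromosome lengths must be positive", call. = FALSE)
  setNames(sizes, as.character(df[[1]]))
}

#' Read a BED12 gene annotation
#'
#' Builds gene models from BED12 records: the TSS is the strand-aware 5' end
#' of the span, exons come from blockSizes/blockStarts, and the 5' UTR is
#' derived from thickStart/thickEnd (interpreted as the CDS span) on the
#' first exon(s) upstream of the CDS.
#'
#' @param path BED12 file, tab-separated, no header
#' @return a `gene_annotation` object; see [gene_annotation()]
#' @export
read_bed12_genes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("BED12 annotation needs 12 columns", call. = FALSE)
  names(df)[1:12] <- c("chrom", "start", "end", "name", "score", "strand",
                       "thickStart", "thickEnd", "rgb", "blockCount",
                       "blockSizes", "blockStarts")
  genes <- exons <- utr5 <- list()
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    sizes <- as.integer(strsplit(sub(",$", "", r$blockSizes), ",")[[1]])
    starts <- as.integer(strsplit(sub(",$", "", r$blockStarts), ",")[[1]])
    ex_start <- r$start + starts
    ex_end <- ex_start + sizes
    tss <- if (r$strand == "-") r$end - 1L else r$start
    genes[[i]] <- data.frame(
      gene_id = r$name, chrom = r$chrom, strand = r$strand,
      start = r$start, end = r$end, tss = tss, stringsAsFactors = FALSE
    )
    exons[[i]] <- data.frame(
      gene_id = r$name, chrom = r$chrom, start = ex_start, end = ex_end,
      stringsAsFactors = FALSE
    )
    # 5' UTR: exonic sequence strictly 5' of the CDS (thick) span.
    if (r$thickEnd > r$thickStart) {
      if (r$strand == "-") {
        u_start <- pmax(ex_start, r$thickEnd); u_end <- ex_end
      } else {
        u_start <- ex_start; u_end <- pmin(ex_end, r$thickStart)
      }
      keep <- u_end > u_start
      if (any(keep)) {
        utr5[[length(utr5) + 1L]] <- data.frame(
          gene_id = r$name, chrom = r$chrom,
          start = u_start[keep], end = u_end[keep], stringsAsFactors = FALSE
        )
      }
    }
  }
  gene_annotation(
    genes = do.call(rbind, genes),
    exons = do.call(rbind, exons),
    utr5 = if (length(utr5)) do.call(rbind, utr5) else NULL
  )
}

#' Construct a gene annotation object
#'
#' @param genes data.frame with gene_id, chrom, strand, start, end, tss
#'   (0-based half-open span; tss is a 0-based position inside the span)
#' @param exons data.frame with gene_id, chrom, start, end
#' @param utr5 optional data.frame with gene_id, chrom, start, end
#' @return list of the three tables with class `gene_annotation`
#' @export
gene_annotation <- function(genes, exons, utr5 = NULL) {
  check_intervals(genes, "gene span")
  check_intervals(exons, "exon")
  if (!is.null(utr5) && nrow(utr5)) check_intervals(utr5, "5' UTR")
  if (nrow(genes)) {
    if (any(genes$tss < genes$start | genes$tss >= genes$end)) {
      stop("TSS must lie within the gene span", call. = FALSE)
    }
    span <- genes[match(exons$gene_id, genes$gene_id), ]
    if (any(exons$start < span$start | exons$end > span$end)) {
      stop("exons must lie within their gene span", call. = FALSE)
    }
    # exons of one gene must be non-overlapping once sorted
    for (g in unique(exons$gene_id)) {
      e <- exons[exons$gene_id == g, ]
      e <- e[order(e$start), ]
      if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
        stop("overlapping exons in gene ", g, call. = FALSE)
      }
    }
  }
  structure(list(genes = genes, exons = exons,
                 utr5 = utr5 %||% data.frame(gene_id = character(), chrom = character(),
                                             start = integer(), end = integer())),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes,", nrow(x$exons), "exons,",
      nrow(x$utr5), "5'UTR blocks on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Write a gene annotation as BED12
#'
#' @param annotation a `gene_annotation`
#' @param path output path
#' @return invisibly, the path
#' @export
write_bed12_genes <- function(annotation, path) {
  g <- annotation$genes
  rows <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    ex <- annotation$exons[annotation$exons$gene_id == g$gene_id[i], ]
    ex <- ex[order(ex$start), ]
    ut <- annotation$utr5[annotation$utr5$gene_id == g$gene_id[i], ]
    # thick (CDS) span = gene span minus the 5' UTR extent
    thick_start <- g$start[i]; thick_end <- g$end[i]
    if (nrow(ut)) {
      if (g$strand[i] == "-") thick_end <- min(ut$start) else thick_start <- max(ut$end)
    }
    rows[i] <- paste(
      g$chrom[i], g$start[i], g$end[i], g$gene_id[i], 0, g$strand[i],
      thick_start, thick_end, "0",
      nrow(ex),
      paste0(paste(ex$end - ex$start, collapse = ","), ","),
      paste0(paste(ex$start - g$start[i], collapse = ","), ","),
      sep = "\t"
    )
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read a counts TSV (feature_id then one column per sample)
#'
#' @param path tab-separated file with a header row
#' @param feature_lengths optional named vector of feature lengths (bp)
#' @return a raw [count_matrix()]
#' @export
read_counts_tsv <- function(path, feature_lengths = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  count_matrix(m, feature_lengths = feature_lengths)
}

#' Read a GMT gene-set collection
#'
#' Each line: set name, description, then tab-separated gene ids.
#'
#' @param path GMT file
#' @return named list of character vectors of gene ids
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop("GMT line needs name, description and >=1 gene", call. = FALSE)
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors
#' @param path output path
#' @param description description field (recycled)
#' @return invisibly, the path
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
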