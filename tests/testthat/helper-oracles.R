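# Independent brute-force oracles: every interval question is answered by
# enumerating base positions, every enrichment statistic by explicit
# step-by-step computation, independent of the package's code paths.

# Per-base membership set of a 0-based half-open interval.
bases <- function(start, end) seq.int(start, end - 1L)

oracle_overlap_fraction <- function(a, b) {
  if (as.character(a$chrom) != as.character(b$chrom)) return(0)
  ov <- length(intersect(bases(a$start, a$end), bases(b$start, b$end)))
  ov / min(a$end - a$start, b$end - b$start)
}

# Transitive clustering + support filter + hull merge, all by enumeration.
oracle_aggregate <- function(df, min_overlap) {
  n <- nrow(df)
  if (n == 0) return(df[0, c("chrom", "start", "end")])
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- i != j &&
        oracle_overlap_fraction(df[i, ], df[j, ]) >= min_overlap
    }
  }
  cl <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && cl[j] != cl[i]) {
        cl[cl == cl[j]] <- cl[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  hulls <- do.call(rbind, lapply(unique(cl), function(c0) {
    idx <- which(cl == c0)
    if (length(unique(df$replicate_id[idx])) < 2) return(NULL)
    data.frame(chrom = df$chrom[idx[1]], start = min(df$start[idx]),
               end = max(df$end[idx]),
               support = length(unique(df$replicate_id[idx])),
               stringsAsFactors = FALSE)
  }))
  if (is.null(hulls)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      support = integer()))
  }
  # merge any-overlap hulls until stable
  repeat {
    merged <- FALSE
    for (i in seq_len(nrow(hulls))) {
      for (j in seq_len(nrow(hulls))) {
        if (i >= j) next
        if (hulls$chrom[i] == hulls$chrom[j] &&
            length(intersect(bases(hulls$start[i], hulls$end[i]),
                             bases(hulls$start[j], hulls$end[j]))) > 0) {
          hulls$start[i] <- min(hulls$start[i], hulls$start[j])
          hulls$end[i] <- max(hulls$end[i], hulls$end[j])
          hulls$support[i] <- max(hulls$support[i], hulls$support[j])
          hulls <- hulls[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  hulls <- hulls[order(hulls$chrom, hulls$start), , drop = FALSE]
  rownames(hulls) <- NULL
  hulls
}

# Any-overlap union by per-base membership, returned as maximal runs.
oracle_union <- function(dfs) {
  all <- do.call(rbind, lapply(dfs, function(d) d[, c("chrom", "start", "end")]))
  out <- list()
  for (ch in sort(unique(all$chrom))) {
    d <- all[all$chrom == ch, ]
    covered <- sort(unique(unlist(Map(bases, d$start, d$end))))
    if (length(covered) == 0) next
    breaks <- which(diff(covered) > 1)
    run_start <- covered[c(1, breaks + 1)]
    run_end <- covered[c(breaks, length(covered))] + 1L
    out[[ch]] <- data.frame(chrom = ch, start = run_start, end = run_end,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Step-by-step preranked running-sum oracle.
oracle_es <- function(genes, scores, set, p = 1) {
  ord <- order(-scores)
  genes <- genes[ord]; scores <- scores[ord]
  hit <- genes %in% set
  nh <- sum(hit)
  n <- length(genes)
  denom <- sum(abs(scores[hit])^p)
  run <- 0; mx <- -Inf; mn <- Inf
  for (i in seq_len(n)) {
    if (hit[i]) {
      run <- run + if (denom > 0) abs(scores[i])^p / denom else 1 / nh
    } else {
      run <- run - 1 / (n - nh)
    }
    mx <- max(mx, run); mn <- min(mn, run)
  }
  # positive extremum wins magnitude ties (same rule as the implementation)
  if (mx >= -mn - 1e-12) mx else mn
}

# Exhaustive ORA p-value: enumerate every query of size n from the universe
# and count those with overlap >= observed.
oracle_ora_p <- function(query, gene_set, universe) {
  k <- length(intersect(query, gene_set))
  combos <- utils::combn(universe, length(query), simplify = FALSE)
  mean(vapply(combos, function(q) length(intersect(q, gene_set)) >= k, TRUE))
}

# Random interval table on a 1-2 chromosome toy genome.
random_intervals <- function(n, max_pos = 300, max_len = 60, chroms = "chr1") {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len, stringsAsFactors = FALSE)
}
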