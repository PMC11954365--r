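# Self-contained gene-set statistics: an exact hypergeometric
# over-representation test and a preranked weighted Kolmogorov-Smirnov
# enrichment score with a gene-label permutation null. These are authored
# here rather than delegated so the statistic itself is testable against
# brute-force oracles.

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of drawing at least the observed overlap between a
#' query and a gene set when sampling |query| genes from the universe
#' without replacement. The odds ratio comes from the 2x2 table with a
#' Haldane 0.5 correction when any cell is zero.
#'
#' @param query character vector of query gene ids (subset of universe)
#' @param gene_set character vector of set gene ids (subset of universe)
#' @param universe character vector of all gene ids
#' @return list: overlap, p_value, odds_ratio, expected, genes (the overlap)
#' @export
hypergeometric_ora <- function(query, gene_set, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  query <- unique(as.character(query))
  gene_set <- unique(as.character(gene_set))
  if (!all(query %in% universe) || !all(gene_set %in% universe)) {
    stop("query and gene_set must be subsets of the universe", call. = FALSE)
  }
  N <- length(universe); K <- length(gene_set); n <- length(query)
  hit <- intersect(query, gene_set)
  k <- length(hit)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tab <- c(a = k, b = n - k, c = K - k, d = N - K - n + k)
  if (any(tab == 0)) tab <- tab + 0.5
  odds <- (tab["a"] * tab["d"]) / (tab["b"] * tab["c"])
  list(
    overlap = k,
    p_value = p,
    odds_ratio = unname(odds),
    expected = n * K / N,
    genes = hit
  )
}

# Core running-sum computation shared by the observed statistic and the
# permutation null: `hit` is a logical vector along the ranking.
running_es <- function(scores, hit, weight_p) {
  n <- length(scores)
  nh <- sum(hit)
  w <- abs(scores[hit])^weight_p
  if (sum(w) == 0) w <- rep(1, nh)  # all-zero hit scores: equal weights
  inc <- numeric(n)
  inc[hit] <- w / sum(w)
  miss_dec <- if (n > nh) 1 / (n - nh) else 0
  inc[!hit] <- -miss_dec
  cumsum(inc)
}

#' Preranked enrichment score (weighted Kolmogorov-Smirnov statistic)
#'
#' Walks the ranking from top to bottom, incrementing the running sum by
#' |score|^p / sum over hits at set members and decrementing by 1/(N - Nh)
#' elsewhere. The enrichment score is the extremum of largest magnitude
#' (first such position on ties). The leading edge is the set members at or
#' before a positive extremum, or at or after a negative one.
#'
#' @param ranked data.frame with columns gene and score, or a named numeric
#'   vector; sorted by decreasing score internally (ties keep input order)
#' @param gene_set character vector of set members (must intersect the
#'   ranking)
#' @param weight_p score weight exponent (default 1; 0 gives the classic KS
#'   statistic)
#' @details When the positive and negative extrema of the running sum tie in
#'   magnitude (possible with the rational miss decrements), the positive
#'   extremum wins; the comparison uses a 1e-12 tolerance so the tie-break
#'   does not depend on floating-point summation order.
#' @return list: es, running (the running sum), leading_edge, n_hits
#' @export
preranked_es <- function(ranked, gene_set, weight_p = 1) {
  r <- as_ranked(ranked)
  hit <- r$gene %in% gene_set
  if (!any(hit)) stop("gene_set is disjoint from the ranking", call. = FALSE)
  running <- running_es(r$score, hit, weight_p)
  mx <- max(running); mn <- min(running)
  if (mx >= -mn - 1e-12) {
    i <- which.max(running); es <- mx
  } else {
    i <- which.min(running); es <- mn
  }
  leading <- if (es >= 0) r$gene[seq_len(i)][hit[seq_len(i)]]
             else r$gene[i:length(r$gene)][hit[i:length(r$gene)]]
  list(es = es, running = running, leading_edge = leading, n_hits = sum(hit))
}

as_ranked <- function(ranked) {
  if (is.numeric(ranked) && !is.null(names(ranked))) {
    ranked <- data.frame(gene = names(ranked), score = unname(ranked),
                         stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(ranked), all(c("gene", "score") %in% names(ranked)))
  if (anyDuplicated(ranked$gene)) {
    stop("duplicate genes in the ranking", call. = FALSE)
  }
  ranked <- ranked[order(-ranked$score), , drop = FALSE]
  rownames(ranked) <- NULL
  ranked
}

#' Preranked enrichment with a gene-label permutation null
#'
#' The null distribution of the enrichment score comes from `n_perm` random
#' same-size gene sets drawn from the ranking. NES is the observed score
#' divided by the mean |null score| of the same sign; the p-value is
#' (1 + #null as or more extreme) / (1 + n_perm), where "as or more extreme"
#' compares magnitudes (|null ES| >= |ES|) so the test stays calibrated even
#' though the sign of the observed score is data-chosen.
#'
#' @inheritParams preranked_es
#' @param n_perm number of permutations (>= 100)
#' @param seed RNG seed for reproducibility (restores the caller's RNG state)
#' @return list: es, nes, p_value, leading_edge, n_hits, null_es
#' @export
preranked_significance <- function(ranked, gene_set, weight_p = 1,
                                   n_perm = 1000, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  r <- as_ranked(ranked)
  obs <- preranked_es(r, gene_set, weight_p)
  n <- nrow(r); nh <- obs$n_hits
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      hit <- logical(n)
      hit[sample.int(n, nh)] <- TRUE
      running <- running_es(r$score, hit, weight_p)
      mx <- max(running); mn <- min(running)
      if (mx >= -mn - 1e-12) mx else mn
    }, 0)
  })
  same_sign <- null_es[sign(null_es) == sign(obs$es)]
  nes <- if (length(same_sign)) obs$es / mean(abs(same_sign))
         else obs$es / mean(abs(null_es))
  extreme <- sum(abs(null_es) >= abs(obs$es))
  list(
    es = obs$es,
    nes = nes,
    p_value = (1 + extreme) / (1 + n_perm),
    leading_edge = obs$leading_edge,
    n_hits = nh,
    null_es = null_es
  )
}

#' Preranked enrichment over a gene-set collection
#'
#' Runs [preranked_significance()] per set and BH-adjusts the permutation
#' p-values across sets.
#'
#' @inheritParams preranked_significance
#' @param sets named list of gene sets (sets disjoint from the ranking are
#'   skipped with a warning)
#' @return data.frame: set, es, nes, p_value, q_value, n_hits, leading_edge
#'   (comma-separated)
#' @export
preranked_collection <- function(ranked, sets, weight_p = 1, n_perm = 1000,
                                 seed = NULL) {
  r <- as_ranked(ranked)
  usable <- vapply(sets, function(s) any(r$gene %in% s), TRUE)
  if (any(!usable)) {
    warning(sum(!usable), " gene set(s) disjoint from the ranking were skipped")
  }
  sets <- sets[usable]
  seeds <- if (is.null(seed)) rep(list(NULL), length(sets))
           else as.list(seed + seq_along(sets))
  rows <- lapply(seq_along(sets), function(i) {
    res <- preranked_significance(r, sets[[i]], weight_p, n_perm, seeds[[i]])
    data.frame(
      set = names(sets)[i], es = res$es, nes = res$nes, p_value = res$p_value,
      n_hits = res$n_hits,
      leading_edge = paste(res$leading_edge, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out[, c("set", "es", "nes", "p_value", "q_value", "n_hits", "leading_edge")]
}

#' ORA over a gene-set collection
#'
#' @inheritParams hypergeometric_ora
#' @param sets named list of gene sets
#' @return data.frame: set, overlap, expected, odds_ratio, p_value, q_value
#' @export
ora_collection <- function(query, sets, universe) {
  rows <- lapply(names(sets), function(nm) {
    res <- hypergeometric_ora(query, intersect(sets[[nm]], universe), universe)
    data.frame(set = nm, overlap = res$overlap, expected = res$expected,
               odds_ratio = res$odds_ratio, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out
}

#' Top k most enriched sets
#'
#' Orders by smallest p, breaking ties by larger |NES| (or odds ratio for
#' ORA results), then by set name, and returns the first `k`.
#'
#' @param results data.frame with columns set, p_value and either nes or
#'   odds_ratio
#' @param k number of sets to keep (default 10)
#' @return the ordered subset
#' @export
top_enriched <- function(results, k = 10) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  strength <- if ("nes" %in% names(results)) abs(results$nes)
              else if ("odds_ratio" %in% names(results)) results$odds_ratio
              else rep(0, nrow(results))
  ord <- order(results$p_value, -strength, results$set)
  out <- results[ord, , drop = FALSE][seq_len(min(k, nrow(results))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
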