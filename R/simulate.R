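# Coupled synthetic ChIP/ATAC/RNA generator with a planted direct-target
# taxonomy. Two genotypes (WT, KO) x n_replicates; bound genes carry a
# promoter-proximal ChIP peak; planted accessibility and expression effects
# follow the four-category mechanism taxonomy so end-to-end recovery can be
# scored against known truth. Count noise is negative-binomial-like via a
# Poisson-Gamma mixture: the Gamma intensity has mean 1 and coefficient of
# variation `nb_dispersion`.

SIM_STAGES <- c("genome", "truth", "chip", "atac", "rna", "sets")

#' Simulation configuration
#'
#' Defaults define the study conditions: 2 genotypes x 2 replicates, 20
#' genes planted per mechanism category with accessibility effect 1.5 and
#' expression effect 2.0 (log2), replicate-private decoy peaks at rate 0.2,
#' and planted features kept to a small fraction of the gene universe so
#' library-size normalization is not distorted by the planted signal.
#'
#' @param seed RNG seed; every stage derives its own sub-seed from it
#' @param n_chroms,chrom_length genome shape (bp per chromosome)
#' @param n_genes number of genes placed (non-overlapping)
#' @param n_per_category genes planted per mechanism category
#' @param n_bound_same bound genes with no expression/accessibility change
#' @param n_unbound_de unbound genes with planted RNA+ATAC changes
#'   (half up, half down) — indirect effects
#' @param n_background_peaks intergenic accessibility peaks far from genes
#' @param lfc_atac,lfc_rna planted log2 effects (KO over WT)
#' @param nb_dispersion coefficient of variation of the Gamma intensity in
#'   the Poisson-Gamma count noise
#' @param reads_per_sample approximate ATAC fragments per sample
#' @param background_frac fraction of fragments scattered outside peaks
#' @param chip_reads_per_peak mean antibody fragments per bound promoter
#' @param peak_width_mean,peak_width_sd peak width distribution (bp)
#' @param replicate_jitter max per-replicate boundary jitter (bp); bounded
#'   so replicate copies of a planted peak always satisfy the 50% rule
#' @param singleton_rate decoy peaks per replicate, as a fraction of the
#'   real peak count; decoys appear in exactly one replicate
#' @param n_replicates replicates per condition (>= 2)
#' @param rna_mean,rna_sdlog,rna_min_mean baseline expression: log-normal
#'   with a floor (planted targets are expressed genes)
#' @param frag_short_frac fraction of sub-nucleosomal (~60 bp) fragments;
#'   the rest are mono-nucleosomal (~200 bp)
#' @return list of settings, class `sim_config`
#' @export
sim_config <- function(seed = 7,
                       n_chroms = 4, chrom_length = 2e6,
                       n_genes = 1000,
                       n_per_category = 20,
                       n_bound_same = 40,
                       n_unbound_de = 40,
                       n_background_peaks = 60,
                       lfc_atac = 1.5, lfc_rna = 2.0,
                       nb_dispersion = 0.2,
                       reads_per_sample = 3e5,
                       background_frac = 0.3,
                       chip_reads_per_peak = 200,
                       peak_width_mean = 400, peak_width_sd = 50,
                       replicate_jitter = 50,
                       singleton_rate = 0.2,
                       n_replicates = 2,
                       rna_mean = 300, rna_sdlog = 1, rna_min_mean = 30,
                       frag_short_frac = 0.55) {
  cfg <- as.list(environment())
  if (cfg$n_genes < 4 * cfg$n_per_category + cfg$n_bound_same + cfg$n_unbound_de) {
    stop("n_genes too small for the planted taxonomy", call. = FALSE)
  }
  if (cfg$lfc_atac <= 0 || cfg$lfc_rna <= 0) stop("planted effects must be > 0", call. = FALSE)
  if (cfg$singleton_rate < 0 || cfg$singleton_rate > 1 ||
      cfg$background_frac < 0 || cfg$background_frac >= 1 ||
      cfg$frag_short_frac < 0 || cfg$frag_short_frac > 1) {
    stop("rates must be probabilities", call. = FALSE)
  }
  if (cfg$n_replicates < 2) stop("need >= 2 replicates", call. = FALSE)
  if (cfg$replicate_jitter * 2 > cfg$peak_width_mean / 2) {
    stop("replicate_jitter too large for the 50% overlap guarantee", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# Per-stage sub-seed, deterministic in cfg$seed and the stage name.
stage_seed <- function(seed, stage) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(SIM_STAGES)))
  seeds[match(stage, SIM_STAGES)]
}

# Gamma multiplier with mean 1 and CV = cv (cv = 0 returns 1s).
gamma_intensity <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  shape <- 1 / cv^2
  rgamma(n, shape = shape, rate = shape)
}

#' Simulate the genome and gene annotation
#'
#' Genes are placed left to right with random intergenic gaps; dedicated
#' wide gaps host background accessibility peaks (and later decoys) at
#' least 6 kb from any TSS so they never acquire a gene assignment.
#'
#' @param cfg a [sim_config()]
#' @return list: genome (named lengths), annotation ([gene_annotation()]),
#'   background (data.frame of background peak anchors)
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(stage_seed(cfg$seed, "genome"), {
    footprint <- 2000 + 3000  # mean gene span + mean gap
    total <- cfg$n_chroms * cfg$chrom_length
    if (cfg$n_genes * footprint + cfg$n_background_peaks * 14000 > total) {
      stop("infeasible packing: genome too small for n_genes", call. = FALSE)
    }
    genome <- setNames(rep(as.integer(cfg$chrom_length), cfg$n_chroms),
                       sprintf("chr%d", seq_len(cfg$n_chroms)))

    kinds <- sample(c(rep("gene", cfg$n_genes), rep("bg", cfg$n_background_peaks)))
    genes <- exons <- utr5 <- vector("list", cfg$n_genes)
    bg <- vector("list", cfg$n_background_peaks)
    gi <- bi <- 0L
    ci <- 1L; cursor <- 0
    width_digits <- max(4L, nchar(as.character(cfg$n_genes)))
    for (kind in kinds) {
      if (kind == "gene") {
        span <- round(runif(1, 1600, 2400))
        gap <- round(runif(1, 2000, 4000))
        need <- gap + span
      } else {
        span <- 14000
        gap <- 0
        need <- span
      }
      while (cursor + need > genome[ci] - 1000) {
        ci <- ci + 1L; cursor <- 0
        if (ci > cfg$n_chroms) stop("infeasible packing: ran out of genome", call. = FALSE)
      }
      chrom <- names(genome)[ci]
      s <- as.integer(cursor + gap)
      if (kind == "gene") {
        gi <- gi + 1L
        e <- s + as.integer(span)
        strand <- sample(c("+", "-"), 1)
        gid <- sprintf(paste0("gene%0", width_digits, "d"), gi)
        tss <- if (strand == "-") e - 1L else s
        # three exons at fixed span fractions; first exon holds the 5' UTR
        b <- s + as.integer(round(span * c(0, 0.15, 0.40, 0.55, 0.85, 1)))
        ex <- data.frame(gene_id = gid, chrom = chrom,
                         start = b[c(1, 3, 5)], end = b[c(2, 4, 6)],
                         stringsAsFactors = FALSE)
        u <- if (strand == "-") data.frame(gene_id = gid, chrom = chrom,
                                           start = e - 150L, end = e,
                                           stringsAsFactors = FALSE)
             else data.frame(gene_id = gid, chrom = chrom,
                             start = s, end = s + 150L, stringsAsFactors = FALSE)
        genes[[gi]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                                  start = s, end = e, tss = tss,
                                  stringsAsFactors = FALSE)
        exons[[gi]] <- ex
        utr5[[gi]] <- u
      } else {
        bi <- bi + 1L
        bg[[bi]] <- data.frame(name = sprintf("bg%04d", bi), chrom = chrom,
                               center = s + 7000L, stringsAsFactors = FALSE)
      }
      cursor <- cursor + need
    }
    empty_genes <- data.frame(gene_id = character(), chrom = character(),
                              strand = character(), start = integer(),
                              end = integer(), tss = integer())
    empty_iv <- data.frame(gene_id = character(), chrom = character(),
                           start = integer(), end = integer())
    annotation <- gene_annotation(
      genes = do.call(rbind, genes) %||% empty_genes,
      exons = do.call(rbind, exons) %||% empty_iv,
      utr5 = do.call(rbind, utr5) %||% empty_iv
    )
    list(genome = genome, annotation = annotation,
         background = if (bi > 0) do.call(rbind, bg)
                      else data.frame(name = character(), chrom = character(),
                                      center = integer()))
  })
}

#' Plant the gene taxonomy and effect sizes
#'
#' Randomly assigns genes to the four mechanism categories (bound, RNA and
#' ATAC both changed), a bound-but-unchanged group, an unbound-but-changed
#' group (indirect effects, half up half down), and a null remainder; draws
#' baseline expression and per-peak accessibility intensity.
#'
#' @param cfg a [sim_config()]
#' @param sim result of [simulate_genome()]
#' @return data.frame truth table: gene_id, bound, rna_class, atac_class,
#'   mechanism, rna_lfc, atac_lfc, rna_mu, atac_lambda
#' @export
plant_taxonomy <- function(cfg, sim) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- sim$annotation$genes
  with_seed(stage_seed(cfg$seed, "truth"), {
    ids <- sample(genes$gene_id)
    k <- cfg$n_per_category
    groups <- list(
      repressed_via_closing = c(TRUE, "up", "up"),
      repressed_via_opening = c(TRUE, "up", "down"),
      activated_via_closing = c(TRUE, "down", "up"),
      activated_via_opening = c(TRUE, "down", "down")
    )
    truth <- data.frame(
      gene_id = ids, bound = FALSE, rna_class = "same", atac_class = "same",
      mechanism = "unresolved", stringsAsFactors = FALSE
    )
    pos <- 0L
    for (nm in names(groups)) {
      idx <- pos + seq_len(k); pos <- pos + k
      truth$bound[idx] <- TRUE
      truth$rna_class[idx] <- groups[[nm]][2]
      truth$atac_class[idx] <- groups[[nm]][3]
      truth$mechanism[idx] <- nm
    }
    idx <- pos + seq_len(cfg$n_bound_same); pos <- pos + cfg$n_bound_same
    truth$bound[idx] <- TRUE
    half <- cfg$n_unbound_de %/% 2
    idx <- pos + seq_len(half); pos <- pos + half
    truth$rna_class[idx] <- "up"; truth$atac_class[idx] <- "up"
    idx <- pos + seq_len(cfg$n_unbound_de - half); pos <- pos + cfg$n_unbound_de - half
    truth$rna_class[idx] <- "down"; truth$atac_class[idx] <- "down"

    sgn <- function(cl) ifelse(cl == "up", 1, ifelse(cl == "down", -1, 0))
    truth$rna_lfc <- sgn(truth$rna_class) * cfg$lfc_rna
    truth$atac_lfc <- sgn(truth$atac_class) * cfg$lfc_atac
    truth$rna_mu <- pmax(rlnorm(nrow(truth), log(cfg$rna_mean), cfg$rna_sdlog),
                         cfg$rna_min_mean)
    lambda_base <- (1 - cfg$background_frac) * cfg$reads_per_sample /
      (cfg$n_genes + cfg$n_background_peaks)
    truth$atac_lambda <- lambda_base * rlnorm(nrow(truth), 0, 0.25)
    truth <- truth[match(genes$gene_id, truth$gene_id), , drop = FALSE]
    rownames(truth) <- NULL
    truth
  })
}

# Peak interval of given width centered on a position, clipped to [0, len).
centered_peak <- function(chrom, center, width, genome) {
  half <- as.integer(round(width / 2))
  start <- pmax(0L, as.integer(center) - half)
  end <- pmin(unname(genome[as.character(chrom)]), as.integer(center) + half)
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

# Jitter both boundaries of each interval by up to +/- jitter bp.
jitter_peaks <- function(df, jitter, genome) {
  if (jitter <= 0 || nrow(df) == 0) return(df)
  s <- df$start + as.integer(round(runif(nrow(df), -jitter, jitter)))
  e <- df$end + as.integer(round(runif(nrow(df), -jitter, jitter)))
  df$start <- pmax(0L, s)
  df$end <- pmin(unname(genome[as.character(df$chrom)]), pmax(e, df$start + 50L))
  df
}

# Place n decoy peaks uniformly, rejecting candidates that come within
# `pad` bp of `occupied` intervals or of each other.
place_decoys <- function(n, width, occupied, genome, pad = 1000) {
  if (n <= 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  placed <- occupied[, c("chrom", "start", "end"), drop = FALSE]
  out <- list()
  got <- 0L
  for (iter in 1:50) {
    m <- (n - got) * 3L
    chrom <- sample(names(genome), m, replace = TRUE,
                    prob = as.numeric(genome) / sum(as.numeric(genome)))
    center <- floor(runif(m, width, genome[chrom] - width))
    cand <- centered_peak(chrom, center, width, genome)
    padded <- data.frame(chrom = placed$chrom,
                         start = pmax(0, placed$start - pad),
                         end = placed$end + pad)
    bad <- IRanges::overlapsAny(intervals_to_granges(cand, levels = names(genome)),
                                intervals_to_granges(padded, levels = names(genome)),
                                ignore.strand = TRUE)
    cand <- cand[!bad, , drop = FALSE]
    # greedy self-deconfliction within the batch
    if (nrow(cand) > 1) {
      keep <- rep(TRUE, nrow(cand))
      prs <- overlap_pairs(data.frame(chrom = cand$chrom,
                                      start = pmax(0, cand$start - pad),
                                      end = cand$end + pad), 1e-9)
      if (nrow(prs)) keep[unique(prs[, 2])] <- FALSE
      cand <- cand[keep, , drop = FALSE]
    }
    if (nrow(cand) > n - got) cand <- cand[seq_len(n - got), , drop = FALSE]
    if (nrow(cand)) {
      out[[length(out) + 1L]] <- cand
      placed <- rbind(placed, cand)
      got <- got + nrow(cand)
    }
    if (got >= n) break
  }
  if (got < n) stop("could not place decoy peaks without conflicts", call. = FALSE)
  do.call(rbind, out)
}

# Fragments around peak centers: per-peak counts are Poisson draws of
# lambda, midpoints Gaussian around the center, sizes from the ATAC
# sub-nucleosomal/mono-nucleosomal mixture (or a single ChIP size class).
peak_fragments <- function(peaks, lambda, genome, cfg, size_model = c("atac", "chip")) {
  size_model <- match.arg(size_model)
  counts <- rpois(length(lambda), lambda)
  total <- sum(counts)
  if (total == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  idx <- rep(seq_len(nrow(peaks)), counts)
  center <- (peaks$start[idx] + peaks$end[idx]) / 2
  spread <- (peaks$end[idx] - peaks$start[idx]) / 4
  mids <- rnorm(total, center, spread)
  sizes <- fragment_sizes(total, cfg, size_model)
  build_fragments(peaks$chrom[idx], mids, sizes, genome)
}

fragment_sizes <- function(n, cfg, size_model) {
  if (size_model == "chip") {
    return(pmax(60, round(rnorm(n, 220, 40))))
  }
  short <- runif(n) < cfg$frag_short_frac
  sizes <- numeric(n)
  sizes[short] <- pmax(20, round(rnorm(sum(short), 60, 15)))
  sizes[!short] <- pmax(120, round(rnorm(sum(!short), 200, 20)))
  sizes
}

build_fragments <- function(chrom, mids, sizes, genome) {
  start <- pmax(0L, as.integer(round(mids - sizes / 2)))
  end <- start + as.integer(sizes)
  lim <- unname(genome[as.character(chrom)])
  end <- pmin(end, lim)
  start <- pmin(start, end - 1L)
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

uniform_fragments <- function(n, genome, cfg, size_model = "atac") {
  chrom <- sample(names(genome), n, replace = TRUE,
                  prob = as.numeric(genome) / sum(as.numeric(genome)))
  mids <- floor(runif(n, 300, genome[chrom] - 300))
  sizes <- fragment_sizes(n, cfg, size_model)
  build_fragments(chrom, mids, sizes, genome)
}

#' Simulate the ChIP experiment
#'
#' Bound genes get a promoter-proximal peak present in every replicate
#' (boundaries jittered within the 50% rule); replicate-private decoys are
#' injected at `singleton_rate`; antibody fragments pile up on real peaks
#' over a uniform background while the IgG control is background only.
#'
#' @param cfg a [sim_config()]
#' @param sim result of [simulate_genome()]
#' @param truth result of [plant_taxonomy()]
#' @return list: replicate_peaks (named list per replicate, decoys flagged
#'   in the `decoy` column), fragments (antibody per replicate + igg),
#'   truth_peaks (planted peak per bound gene)
#' @export
simulate_chip <- function(cfg, sim, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  genome <- sim$genome
  with_seed(stage_seed(cfg$seed, "chip"), {
    bound <- merge(truth[truth$bound, "gene_id", drop = FALSE],
                   sim$annotation$genes, by = "gene_id")
    bound <- bound[order(bound$gene_id), , drop = FALSE]
    widths <- pmax(200, round(rnorm(nrow(bound), cfg$peak_width_mean, cfg$peak_width_sd)))
    real <- centered_peak(bound$chrom, bound$tss, widths, genome)
    real$name <- paste0("chip_", bound$gene_id)
    real$gene_id <- bound$gene_id

    n_decoy <- round(cfg$singleton_rate * nrow(real))
    decoy_pool <- place_decoys(n_decoy * cfg$n_replicates, cfg$peak_width_mean,
                               real, genome)
    replicate_peaks <- list()
    fragments <- list(antibody = list(), igg = list())
    n_bg <- round(cfg$background_frac / (1 - cfg$background_frac) *
                    cfg$chip_reads_per_peak * nrow(real))
    for (r in seq_len(cfg$n_replicates)) {
      rp <- jitter_peaks(real[, c("chrom", "start", "end")], cfg$replicate_jitter, genome)
      rp$name <- real$name
      rp$decoy <- FALSE
      if (n_decoy > 0) {
        d <- decoy_pool[((r - 1) * n_decoy + 1):(r * n_decoy), , drop = FALSE]
        d$name <- sprintf("decoy_r%d_%04d", r, seq_len(nrow(d)))
        d$decoy <- TRUE
        rp <- rbind(rp, d)
      }
      rp <- rp[order(rp$chrom, rp$start, rp$end), , drop = FALSE]
      rownames(rp) <- NULL
      rp$replicate_id <- paste0("rep", r)
      replicate_peaks[[paste0("rep", r)]] <- rp

      lam <- cfg$chip_reads_per_peak * gamma_intensity(nrow(real), cfg$nb_dispersion)
      sig <- peak_fragments(real, lam, genome, cfg, size_model = "chip")
      bg <- uniform_fragments(n_bg, genome, cfg, size_model = "chip")
      fragments$antibody[[paste0("rep", r)]] <- rbind(sig, bg)
      fragments$igg[[paste0("rep", r)]] <-
        uniform_fragments(n_bg + round(cfg$chip_reads_per_peak * nrow(real) * 0.2),
                          genome, cfg, size_model = "chip")
    }
    list(replicate_peaks = replicate_peaks, fragments = fragments, truth_peaks = real)
  })
}

#' Simulate the ATAC experiment
#'
#' Every gene promoter carries an accessibility peak; background peaks sit
#' in gene-free gaps. In the KO genotype, peak intensity at a planted gene
#' scales by 2^(+/- lfc_atac); per-sample counts get Poisson-Gamma noise;
#' fragment sizes follow the sub-nucleosomal + mono-nucleosomal mixture.
#' Per-replicate peak calls (jittered, plus replicate-private decoys) are
#' emitted for both genotypes.
#'
#' @inheritParams simulate_chip
#' @return list: replicate_peaks (list WT/KO of per-replicate tables),
#'   fragments (named list, e.g. WT_1 ... KO_n), peaks (planted peak table
#'   with class and per-genotype intensity)
#' @export
simulate_atac <- function(cfg, sim, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  genome <- sim$genome
  with_seed(stage_seed(cfg$seed, "atac"), {
    genes <- sim$annotation$genes[order(sim$annotation$genes$gene_id), , drop = FALSE]
    tr <- truth[match(genes$gene_id, truth$gene_id), , drop = FALSE]
    widths <- pmax(200, round(rnorm(nrow(genes), cfg$peak_width_mean, cfg$peak_width_sd)))
    prom <- centered_peak(genes$chrom, genes$tss, widths, genome)
    prom$name <- paste0("atacp_", genes$gene_id)
    prom$gene_id <- genes$gene_id
    prom$class <- tr$atac_class
    prom$lambda_wt <- tr$atac_lambda
    prom$lambda_ko <- tr$atac_lambda * 2^tr$atac_lfc

    bg <- sim$background
    if (nrow(bg) > 0) {
      bgw <- pmax(200, round(rnorm(nrow(bg), cfg$peak_width_mean, cfg$peak_width_sd)))
      lambda_base <- (1 - cfg$background_frac) * cfg$reads_per_sample /
        (cfg$n_genes + cfg$n_background_peaks)
      bgp <- centered_peak(bg$chrom, bg$center, bgw, genome)
      bgp$name <- paste0("atacbg_", bg$name)
      bgp$gene_id <- NA_character_
      bgp$class <- "same"
      bgp$lambda_wt <- lambda_base * rlnorm(nrow(bg), 0, 0.25)
      bgp$lambda_ko <- bgp$lambda_wt
      peaks <- rbind(prom, bgp)
    } else {
      peaks <- prom
    }

    n_decoy <- round(cfg$singleton_rate * nrow(peaks))
    decoy_pool <- place_decoys(n_decoy * cfg$n_replicates * 2, cfg$peak_width_mean,
                               peaks, genome)
    replicate_peaks <- list(WT = list(), KO = list())
    fragments <- list()
    n_bg_frag <- round(cfg$background_frac * cfg$reads_per_sample)
    di <- 0L
    for (geno in c("WT", "KO")) {
      lam0 <- if (geno == "WT") peaks$lambda_wt else peaks$lambda_ko
      for (r in seq_len(cfg$n_replicates)) {
        rp <- jitter_peaks(peaks[, c("chrom", "start", "end")], cfg$replicate_jitter, genome)
        rp$name <- peaks$name
        rp$decoy <- FALSE
        if (n_decoy > 0) {
          d <- decoy_pool[di + seq_len(n_decoy), , drop = FALSE]
          di <- di + n_decoy
          d$name <- sprintf("decoy_%s_r%d_%04d", geno, r, seq_len(nrow(d)))
          d$decoy <- TRUE
          rp <- rbind(rp, d)
        }
        rp <- rp[order(rp$chrom, rp$start, rp$end), , drop = FALSE]
        rownames(rp) <- NULL
        rp$replicate_id <- paste0(geno, "_rep", r)
        replicate_peaks[[geno]][[paste0("rep", r)]] <- rp

        lam <- lam0 * gamma_intensity(nrow(peaks), cfg$nb_dispersion)
        sig <- peak_fragments(peaks, lam, genome, cfg, size_model = "atac")
        bgf <- uniform_fragments(n_bg_frag, genome, cfg, size_model = "atac")
        fragments[[paste(geno, r, sep = "_")]] <- rbind(sig, bgf)
      }
    }
    list(replicate_peaks = replicate_peaks, fragments = fragments, peaks = peaks)
  })
}

#' Simulate the RNA count matrix
#'
#' Gene counts are Poisson-Gamma (negative-binomial-like) around a
#' log-normal baseline, with the KO mean scaled by 2^(+/- lfc_rna) at
#' planted genes. Feature lengths are exonic lengths, ready for TPM.
#'
#' @inheritParams simulate_chip
#' @return a raw [count_matrix()], genes x (WT_1..WT_n, KO_1..KO_n)
#' @export
simulate_rna <- function(cfg, sim, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(stage_seed(cfg$seed, "rna"), {
    genes <- sim$annotation$genes
    tr <- truth[match(genes$gene_id, truth$gene_id), , drop = FALSE]
    samples <- c(paste0("WT_", seq_len(cfg$n_replicates)),
                 paste0("KO_", seq_len(cfg$n_replicates)))
    m <- matrix(0L, nrow = nrow(genes), ncol = length(samples),
                dimnames = list(genes$gene_id, samples))
    for (j in seq_along(samples)) {
      ko <- grepl("^KO", samples[j])
      mu <- tr$rna_mu * if (ko) 2^tr$rna_lfc else 1
      m[, j] <- rpois(nrow(genes), mu * gamma_intensity(nrow(genes), cfg$nb_dispersion))
    }
    ex <- sim$annotation$exons
    exlen <- tapply(ex$end - ex$start, ex$gene_id, sum)
    count_matrix(m, feature_lengths = setNames(as.numeric(exlen), names(exlen)))
  })
}

#' Synthetic gene-set collection coupled to the planted truth
#'
#' One set per mechanism category (the planted genes plus a few random
#' extras, hallmark-style) and additional random sets, usable for both ORA
#' and preranked enrichment.
#'
#' @inheritParams simulate_chip
#' @param n_random number of fully random sets
#' @param set_size size of the random sets
#' @return named list of gene-id vectors
#' @export
simulate_gene_sets <- function(cfg, sim, truth, n_random = 6, set_size = 50) {
  with_seed(stage_seed(cfg$seed, "sets"), {
    all_genes <- sim$annotation$genes$gene_id
    sets <- list()
    for (nm in MECHANISMS) {
      planted <- truth$gene_id[truth$mechanism == nm]
      extra <- sample(setdiff(all_genes, planted), max(5, round(length(planted) / 2)))
      sets[[paste0("PLANTED_", toupper(nm))]] <- c(planted, extra)
    }
    for (i in seq_len(n_random)) {
      sets[[sprintf("RANDOM_SET_%02d", i)]] <- sample(all_genes, set_size)
    }
    sets
  })
}

#' Run the whole generator
#'
#' @param cfg a [sim_config()]
#' @return list with cfg, genome, annotation, background, truth, chip,
#'   atac, rna, gene_sets; class `sim_experiment`
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  sim <- simulate_genome(cfg)
  truth <- plant_taxonomy(cfg, sim)
  structure(list(
    cfg = cfg,
    genome = sim$genome,
    annotation = sim$annotation,
    background = sim$background,
    truth = truth,
    chip = simulate_chip(cfg, sim, truth),
    atac = simulate_atac(cfg, sim, truth),
    rna = simulate_rna(cfg, sim, truth),
    gene_sets = simulate_gene_sets(cfg, sim, truth)
  ), class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("sim_experiment:", length(x$genome), "chromosomes,",
      nrow(x$annotation$genes), "genes,",
      sum(x$truth$mechanism != "unresolved"), "planted mechanism genes\n")
  invisible(x)
}

#' Score recovery of the planted taxonomy
#'
#' @param predicted direct-target table from [classify_mechanism()]
#' @param truth truth table from [plant_taxonomy()]
#' @return list: per_category (data.frame with planted, predicted,
#'   recovered, recall, precision per mechanism), confusion (table of
#'   planted vs predicted mechanism)
#' @export
score_recovery <- function(predicted, truth) {
  if (!all(predicted$gene_id %in% truth$gene_id)) {
    stop("predicted gene ids are not all in the truth namespace", call. = FALSE)
  }
  pred_mech <- setNames(predicted$mechanism, predicted$gene_id)
  rows <- lapply(MECHANISMS, function(nm) {
    planted <- truth$gene_id[truth$mechanism == nm]
    called <- predicted$gene_id[predicted$mechanism == nm]
    rec <- length(intersect(planted, called))
    data.frame(
      mechanism = nm,
      planted = length(planted),
      predicted = length(called),
      recovered = rec,
      recall = if (length(planted)) rec / length(planted) else NA_real_,
      precision = if (length(called)) rec / length(called) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  got <- pred_mech[truth$gene_id]
  got[is.na(got)] <- "absent"
  list(
    per_category = do.call(rbind, rows),
    confusion = table(planted = truth$mechanism, predicted = got)
  )
}
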