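# Shared fixtures: a hand-built annotation with wide 5' UTRs (so every
# feature class occupies a workable share of the genome), a small
# simulation configuration for cheap end-to-end checks, and one cached
# default-condition pipeline run shared by the heavier tests.

# 100 plus-strand genes, span 4 kb each: exon1 [0,1000) all 5' UTR, then
# two coding exons; placed every 10 kb on a 1 Mb chromosome.
fixture_annotation <- function(n_genes = 100, spacing = 10000) {
  s <- (seq_len(n_genes) - 1L) * spacing + 2000L
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)), chrom = "chr1", strand = "+",
    start = s, end = s + 4000L, tss = s, stringsAsFactors = FALSE
  )
  exons <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    data.frame(gene_id = genes$gene_id[i], chrom = "chr1",
               start = s[i] + c(0L, 1500L, 3000L),
               end = s[i] + c(1000L, 2500L, 4000L), stringsAsFactors = FALSE)
  }))
  utr5 <- data.frame(gene_id = genes$gene_id, chrom = "chr1",
                     start = s, end = s + 1000L, stringsAsFactors = FALSE)
  gene_annotation(genes, exons, utr5)
}

fixture_genome <- function() c(chr1 = 1000000L)

# Down-scaled simulation for unit tests (full defaults are exercised by the
# cached run below and the acceptance tests).
small_sim_cfg <- function(...) {
  args <- list(n_genes = 120, n_per_category = 5, n_bound_same = 10,
               n_unbound_de = 10, n_background_peaks = 10,
               n_chroms = 2, chrom_length = 1e6,
               reads_per_sample = 4e4, chip_reads_per_peak = 100)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

.run_cache <- new.env(parent = emptyenv())

default_pipeline_run <- function() {
  if (is.null(.run_cache$default)) {
    .run_cache$default <- run_pipeline(
      pipeline_config(),
      out_dir = file.path(tempdir(), "chromtriad_default_run")
    )
  }
  .run_cache$default
}

# A tiny normalized matrix for differential tests.
toy_norm_matrix <- function(values, samples = c("WT_1", "WT_2", "KO_1", "KO_2")) {
  m <- matrix(values, ncol = length(samples),
              dimnames = list(sprintf("f%02d", seq_len(length(values) / length(samples))),
                              samples))
  count_matrix(m, norm_state = "CPM")
}
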