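test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- small_sim_cfg()
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$annotation$genes, b$annotation$genes)
  expect_identical(a$truth, b$truth)
  expect_identical(a$rna$counts, b$rna$counts)
  expect_identical(a$atac$fragments[["KO_1"]], b$atac$fragments[["KO_1"]])
  expect_identical(a$chip$replicate_peaks, b$chip$replicate_peaks)
  c2 <- simulate_experiment(small_sim_cfg(seed = 8))
  expect_false(identical(a$rna$counts, c2$rna$counts))
})

test_that("simulated genes are in bounds, non-overlapping and well-formed", {
  cfg <- small_sim_cfg()
  sim <- simulate_genome(cfg)
  g <- sim$annotation$genes
  expect_equal(nrow(g), cfg$n_genes)
  expect_true(all(g$start >= 0 & g$end <= sim$genome[g$chrom]))
  for (ch in unique(g$chrom)) {
    d <- g[g$chrom == ch, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  # valid annotation object invariants already enforced by constructor;
  # a zero-gene genome is still a valid genome
  empty <- simulate_genome(small_sim_cfg(n_genes = 0, n_per_category = 0,
                                         n_bound_same = 0, n_unbound_de = 0))
  expect_equal(nrow(empty$annotation$genes), 0)
  expect_error(simulate_genome(small_sim_cfg(n_genes = 5000)),
               "infeasible packing")
})

test_that("planted taxonomy category counts match the configuration", {
  cfg <- small_sim_cfg()
  sim <- simulate_genome(cfg)
  truth <- plant_taxonomy(cfg, sim)
  expect_equal(unname(table(truth$mechanism)[c(
    "repressed_via_closing", "repressed_via_opening",
    "activated_via_closing", "activated_via_opening")]),
    rep(cfg$n_per_category, 4), ignore_attr = TRUE)
  expect_equal(sum(truth$bound), 4 * cfg$n_per_category + cfg$n_bound_same)
  expect_equal(sum(truth$rna_class != "same"),
               4 * cfg$n_per_category + cfg$n_unbound_de)
  # effect signs follow the classes
  expect_true(all(truth$rna_lfc[truth$rna_class == "up"] == cfg$lfc_rna))
  expect_true(all(truth$atac_lfc[truth$atac_class == "down"] == -cfg$lfc_atac))
})

test_that("generated files are valid inputs to the readers (round trip)", {
  cfg <- small_sim_cfg()
  exp <- simulate_experiment(cfg)
  p <- withr::local_tempfile(fileext = ".bed")
  rep1 <- exp$chip$replicate_peaks$rep1
  write_bed(rep1, p)
  back <- read_bed(p)
  expect_equal(back[, c("chrom", "start", "end")],
               rep1[order(rep1$chrom, rep1$start, rep1$end),
                    c("chrom", "start", "end")], ignore_attr = TRUE)
  a <- withr::local_tempfile(fileext = ".bed12")
  write_bed12_genes(exp$annotation, a)
  expect_equal(read_bed12_genes(a)$genes, exp$annotation$genes, ignore_attr = TRUE)
  ct <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(exp$rna, ct)
  expect_equal(read_counts_tsv(ct)$counts, exp$rna$counts)
})

test_that("consensus on simulated ChIP removes decoys and keeps planted peaks", {
  # zero jitter: replicate peak lists are identical
  cfg0 <- small_sim_cfg(replicate_jitter = 0, singleton_rate = 0)
  sim <- simulate_genome(cfg0)
  truth <- plant_taxonomy(cfg0, sim)
  chip <- simulate_chip(cfg0, sim, truth)
  expect_identical(chip$replicate_peaks$rep1[, c("chrom", "start", "end")],
                   chip$replicate_peaks$rep2[, c("chrom", "start", "end")])
  cons <- aggregate_replicates(chip$replicate_peaks)
  expect_equal(nrow(cons), nrow(chip$truth_peaks))

  # singleton decoys at rate 0.5: all removed, every planted peak retained
  cfg <- small_sim_cfg(singleton_rate = 0.5)
  sim <- simulate_genome(cfg)
  truth <- plant_taxonomy(cfg, sim)
  chip <- simulate_chip(cfg, sim, truth)
  cons <- aggregate_replicates(chip$replicate_peaks)
  tp <- chip$truth_peaks
  hit <- vapply(seq_len(nrow(tp)), function(i) {
    any(cons$chrom == tp$chrom[i] & cons$start < tp$end[i] & cons$end > tp$start[i])
  }, TRUE)
  expect_gte(mean(hit), 0.99)
  # every consensus peak must trace back to a planted peak (no decoy survives)
  from_real <- vapply(seq_len(nrow(cons)), function(i) {
    any(tp$chrom == cons$chrom[i] & tp$start < cons$end[i] & tp$end > cons$start[i])
  }, TRUE)
  expect_true(all(from_real))
})

test_that("ATAC fragments reproduce the planted intensity and size pattern", {
  # near-zero dispersion, unit effect: KO/WT count ratio converges to 2
  cfg <- small_sim_cfg(nb_dispersion = 1e-9, lfc_atac = 1)
  sim <- simulate_genome(cfg)
  truth <- plant_taxonomy(cfg, sim)
  atac <- simulate_atac(cfg, sim, truth)
  master <- atac$peaks
  master$name <- master$name
  cm <- count_fragments_in_peaks(atac$fragments, master[, c("chrom", "start", "end", "name")])
  up <- master$name[master$class == "up"]
  wt_mean <- rowMeans(cm$counts[up, c("WT_1", "WT_2")])
  ko_mean <- rowMeans(cm$counts[up, c("KO_1", "KO_2")])
  expect_equal(median(ko_mean / wt_mean), 2, tolerance = 0.05)
  same <- master$name[master$class == "same"]
  r_same <- rowMeans(cm$counts[same, c("KO_1", "KO_2")]) /
    rowMeans(cm$counts[same, c("WT_1", "WT_2")])
  expect_equal(median(r_same), 1, tolerance = 0.05)

  qc <- fragment_size_qc(atac$fragments$WT_1)
  expect_gt(qc$fraction_below_100bp, 0.3)
  expect_true(qc$periodicity_flag)
  expect_equal(qc$modal_size, 205, tolerance = 10)
})

test_that("RNA counts are deterministic with calibrated fold changes", {
  cfg <- small_sim_cfg(nb_dispersion = 1e-9, lfc_rna = 1)
  sim <- simulate_genome(cfg)
  truth <- plant_taxonomy(cfg, sim)
  rna <- simulate_rna(cfg, sim, truth)
  up <- truth$gene_id[truth$rna_class == "up"]
  ratio <- rowMeans(rna$counts[up, c("KO_1", "KO_2")]) /
    rowMeans(rna$counts[up, c("WT_1", "WT_2")])
  expect_equal(median(ratio), 2, tolerance = 0.05)

  # default study conditions: planted "same" genes rarely cross the
  # integration cutoff, planted effects are recovered (integer comparison
  # avoids float-ulp artifacts at an exact 95% boundary)
  run <- default_pipeline_run()
  d <- run$rna_integration_diff
  same_genes <- run$truth$gene_id[run$truth$rna_class == "same"]
  ok_same <- sum(d$class[match(same_genes, d$feature_id)] == "same")
  expect_gte(100 * ok_same, 95 * length(same_genes))
  up2 <- run$truth$gene_id[run$truth$rna_class == "up"]
  ok_up <- sum(d$class[match(up2, d$feature_id)] == "up")
  expect_gte(100 * ok_up, 95 * length(up2))
})
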