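test_that("CPM and TPM follow their defining formulas", {
  m <- count_matrix(matrix(c(1, 3), ncol = 1, dimnames = list(c("a", "b"), "s1")))
  cpm <- normalize_counts(m, "CPM")
  expect_equal(unname(cpm$counts[, 1]), c(250000, 750000))

  # single feature: TPM is forced to 1e6
  one <- count_matrix(matrix(42, 1, 1, dimnames = list("a", "s1")),
                      feature_lengths = c(a = 123))
  expect_equal(unname(normalize_counts(one, "TPM")$counts[1, 1]), 1e6)

  # equal counts, lengths 100 and 200 -> TPM ratio 2:1
  two <- count_matrix(matrix(c(50, 50), ncol = 1, dimnames = list(c("a", "b"), "s1")),
                      feature_lengths = c(a = 100, b = 200))
  tpm <- normalize_counts(two, "TPM")
  expect_equal(unname(tpm$counts["a", 1] / tpm$counts["b", 1]), 2)

  expect_error(normalize_counts(two, "CPM") |> normalize_counts("TPM"),
               "already normalized")
  no_len <- count_matrix(matrix(1, 1, 1))
  expect_error(normalize_counts(no_len, "TPM"), "feature_lengths")
  zero <- count_matrix(matrix(0, 2, 1, dimnames = list(c("a", "b"), "s1")))
  expect_error(normalize_counts(zero, "CPM"), "zero column")
})

test_that("TPM columns sum to one million on random matrices", {
  set.seed(71)
  for (i in 1:10) {
    nf <- sample(5:40, 1); ns <- sample(2:6, 1)
    m <- matrix(rpois(nf * ns, 50), nf, ns)
    lens <- setNames(sample(100:5000, nf), sprintf("f%04d", seq_len(nf)))
    rownames(m) <- names(lens)
    tpm <- normalize_counts(count_matrix(m, feature_lengths = lens), "TPM")
    expect_equal(unname(colSums(tpm$counts)), rep(1e6, ns), tolerance = 1e-9)
  }
})

test_that("log2 fold change uses group means with a pseudocount", {
  cm <- toy_norm_matrix(c(10, 10, 43, 43), samples = c("WT_1", "WT_2", "KO_1", "KO_2"))
  d <- classify_differential(cm, c("WT_1", "WT_2"), c("KO_1", "KO_2"),
                             lfc_cutoff = 0.4)
  expect_equal(d$log2fc, log2(44 / 11))  # = 2 exactly
  expect_equal(d$class, "up")

  cm <- toy_norm_matrix(c(10, 10, 10, 10))
  d <- classify_differential(cm, c("WT_1", "WT_2"), c("KO_1", "KO_2"), 0.4)
  expect_equal(d$log2fc, 0)
  expect_equal(d$class, "same")

  # inclusive boundary: |log2FC| exactly at the cutoff is a call
  cm <- toy_norm_matrix(c(9, 9, 19, 19))
  d <- classify_differential(cm, c("WT_1", "WT_2"), c("KO_1", "KO_2"),
                             lfc_cutoff = 1)
  expect_equal(d$log2fc, 1)
  expect_equal(d$class, "up")

  expect_error(classify_differential(cm, "WT_1", "WT_1", 0.4), "overlap")
  raw <- count_matrix(matrix(1:4, 2, 2))
  expect_error(classify_differential(raw, "s01", "s02", 0.4), "normalized")
})

test_that("classes partition features and respond monotonically to the cutoff", {
  set.seed(81)
  for (i in 1:10) {
    nf <- 50
    m <- matrix(rpois(nf * 4, 60) * runif(nf * 4, 0.5, 2), nf, 4,
                dimnames = list(sprintf("f%02d", 1:nf),
                                c("WT_1", "WT_2", "KO_1", "KO_2")))
    cm <- count_matrix(m, norm_state = "CPM")
    cuts <- sort(runif(3, 0.1, 2))
    prev <- NULL
    for (cut in cuts) {
      d <- classify_differential(cm, c("WT_1", "WT_2"), c("KO_1", "KO_2"), cut)
      expect_true(all(d$class %in% c("up", "down", "same")))
      expect_equal(nrow(d), nf)
      if (!is.null(prev)) {
        # raising the cutoff only ever moves features toward "same"
        expect_true(all(d$class == prev$class | d$class == "same"))
      }
      prev <- d
    }
  }
})

test_that("the FDR filter gates calls through BH-adjusted Welch tests", {
  set.seed(91)
  m <- matrix(c(100, 102, 99, 101, 400, 410, 395, 405,   # consistent 2x
                100, 300, 20, 380, 110, 90, 350, 60),    # noisy, inconsistent
              nrow = 2, byrow = TRUE,
              dimnames = list(c("clean", "noisy"),
                              c("WT_1", "WT_2", "WT_3", "WT_4",
                                "KO_1", "KO_2", "KO_3", "KO_4")))
  cm <- count_matrix(m, norm_state = "CPM")
  wt <- paste0("WT_", 1:4); ko <- paste0("KO_", 1:4)
  d <- classify_differential(cm, wt, ko, lfc_cutoff = 0.5,
                             use_fdr = TRUE, q_max = 0.05)
  expect_equal(d$class[d$feature_id == "clean"], "up")
  expect_equal(d$class[d$feature_id == "noisy"], "same")
  expect_true(all(d$q_value >= d$p_value - 1e-12))
  expect_error(classify_differential(cm, "WT_1", ko, 0.5, use_fdr = TRUE),
               ">= 2 samples")
})

test_that("fragment-size QC reports short fraction, mode and periodicity", {
  frag <- function(sizes) data.frame(chrom = "chr1", start = 0L,
                                     end = as.integer(sizes))
  qc <- fragment_size_qc(frag(rep(50, 150)))
  expect_equal(qc$fraction_below_100bp, 1)
  expect_false(qc$periodicity_flag)

  sizes <- c(rep(60, 120), rep(200, 80))  # 60% short + 40% mono-nucleosome
  qc <- fragment_size_qc(frag(sizes))
  expect_equal(qc$fraction_below_100bp, 0.6)
  expect_equal(qc$modal_size, 205)
  expect_true(qc$periodicity_flag)

  set.seed(101)
  qc <- fragment_size_qc(frag(sample(300:400, 500, replace = TRUE)))
  expect_false(qc$periodicity_flag)

  expect_error(fragment_size_qc(frag(rep(50, 99))), ">= 100")
})
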