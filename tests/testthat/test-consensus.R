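rep_peaks <- function(...) {
  # list of per-replicate interval lists -> one table with replicate ids
  reps <- list(...)
  do.call(rbind, lapply(seq_along(reps), function(i) {
    df <- reps[[i]]
    df$replicate_id <- paste0("rep", i)
    df
  }))
}
iv <- function(s, e, ch = "chr1") data.frame(chrom = ch, start = s, end = e)

test_that("replicate aggregation keeps only multi-replicate clusters", {
  # 50% overlap meets the (inclusive) threshold
  cons <- aggregate_replicates(rep_peaks(iv(100, 200), iv(150, 250)))
  expect_equal(cons[, c("start", "end", "support")],
               data.frame(start = 100, end = 250, support = 2),
               ignore_attr = TRUE)
  # below threshold: two singleton clusters, both discarded
  cons <- aggregate_replicates(rep_peaks(iv(100, 200), iv(195, 300)))
  expect_equal(nrow(cons), 0)
  # chained within-sample overlap joins the cluster; orphan removed
  cons <- aggregate_replicates(rep_peaks(rbind(iv(0, 100), iv(500, 600)),
                                         iv(50, 150)))
  expect_equal(cons[, c("start", "end")], data.frame(start = 0, end = 150),
               ignore_attr = TRUE)
  expect_error(aggregate_replicates(iv(0, 10)), "replicate_id")
  one_rep <- iv(0, 10); one_rep$replicate_id <- "rep1"
  expect_error(aggregate_replicates(one_rep), "consensus undefined")
})

test_that("aggregation is invariant to replicate labeling order", {
  set.seed(31)
  for (i in 1:10) {
    df <- random_intervals(12)
    df$replicate_id <- sample(c("rep1", "rep2", "rep3"), 12, replace = TRUE)
    if (length(unique(df$replicate_id)) < 2) next
    a <- aggregate_replicates(df)
    df2 <- df
    df2$replicate_id <- c(rep1 = "B", rep2 = "C", rep3 = "A")[df$replicate_id]
    b <- aggregate_replicates(df2)
    expect_equal(a[, c("chrom", "start", "end", "support")],
                 b[, c("chrom", "start", "end", "support")], ignore_attr = TRUE)
  }
})

test_that("aggregation matches the brute-force oracle on random instances", {
  set.seed(41)
  for (i in 1:25) {
    df <- random_intervals(sample(4:12, 1))
    df$replicate_id <- sample(c("rep1", "rep2"), nrow(df), replace = TRUE)
    if (length(unique(df$replicate_id)) < 2) next
    got <- aggregate_replicates(df, min_overlap = 0.5)
    want <- oracle_aggregate(df, 0.5)
    expect_equal(got[, c("chrom", "start", "end", "support")],
                 want[, c("chrom", "start", "end", "support")],
                 ignore_attr = TRUE)
    # consensus peaks are pairwise disjoint
    if (nrow(got) > 1) {
      expect_true(all(got$start[-1] >= got$end[-nrow(got)] |
                        got$chrom[-1] != got$chrom[-nrow(got)]))
    }
  }
})

test_that("the master list is the any-overlap union across samples", {
  wt <- iv(100, 200); ko <- iv(150, 250)
  m <- union_peak_lists(list(WT = wt, KO = ko))
  expect_equal(m[, c("start", "end")], data.frame(start = 100, end = 250),
               ignore_attr = TRUE)
  expect_equal(m$samples, "KO,WT")
  m <- union_peak_lists(list(WT = iv(100, 200), KO = iv(0, 10)[0, ]))
  expect_equal(nrow(m), 1)
  expect_equal(m$samples, "WT")
  # chained overlaps across three sets collapse into one master peak
  m <- union_peak_lists(list(a = iv(0, 100), b = iv(90, 200), c = iv(190, 300)))
  expect_equal(m[, c("start", "end")], data.frame(start = 0, end = 300),
               ignore_attr = TRUE)

  set.seed(51)
  for (i in 1:25) {
    sets <- lapply(1:3, function(k) random_intervals(sample(2:8, 1),
                                                     chroms = c("chr1", "chr2")))
    got <- union_peak_lists(sets)
    want <- oracle_union(sets)
    expect_equal(got[, c("chrom", "start", "end")], want, ignore_attr = TRUE)
  }
})

test_that("fragment counting follows the midpoint rule and conserves totals", {
  master <- rbind(iv(100, 201), iv(300, 400))
  master$name <- c("p1", "p2")
  # midpoint 200 is inside [100, 201)
  frags <- list(s1 = iv(140, 260))
  cm <- count_fragments_in_peaks(frags, master)
  expect_equal(unname(cm$counts[, "s1"]), c(1L, 0L))
  # fragment wholly outside all peaks is counted nowhere
  cm <- count_fragments_in_peaks(list(s1 = iv(600, 700)), master)
  expect_equal(sum(cm$counts), 0)
  # conservation: uniform fragments over one peak all land in it
  frags <- list(s1 = data.frame(chrom = "chr1", start = 100:199, end = 101:200))
  cm <- count_fragments_in_peaks(frags, master)
  expect_equal(unname(cm$counts["p1", "s1"]), 100L)
  expect_error(count_fragments_in_peaks(list(s1 = iv(0, 10)),
                                        rbind(iv(0, 100), iv(50, 150))),
               "non-overlapping")
  # total assigned never exceeds total fragments
  set.seed(61)
  fr <- random_intervals(200, max_pos = 400)
  m2 <- aggregate_replicates(rep_peaks(iv(0, 120), iv(50, 170)))
  cm <- count_fragments_in_peaks(list(s1 = fr), m2)
  expect_lte(sum(cm$counts), nrow(fr))
})
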