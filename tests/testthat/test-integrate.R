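mk_rna <- function(genes, classes) {
  data.frame(feature_id = genes, mean_a = 1, mean_b = 1, log2fc = 0,
             p_value = NA_real_, q_value = NA_real_, class = classes,
             stringsAsFactors = FALSE)
}

test_that("direct targets are bound AND differentially expressed", {
  rna <- mk_rna(c("A", "B", "C", "D"), c("same", "up", "up", "down"))
  t1 <- call_direct_targets(c("A", "B"), rna)
  expect_equal(t1$gene_id[t1$direct_target], "B")
  expect_equal(nrow(t1), 4)  # covers the whole RNA universe
  t0 <- call_direct_targets(character(), rna)
  expect_false(any(t0$direct_target))
  expect_error(call_direct_targets("A", rna[0, ]), "empty RNA universe")

  set.seed(151)
  for (i in 1:20) {
    genes <- sprintf("g%02d", 1:40)
    bound <- sample(genes, sample(0:30, 1))
    classes <- sample(c("up", "down", "same"), 40, replace = TRUE)
    tt <- call_direct_targets(bound, mk_rna(genes, classes))
    want <- intersect(bound, genes[classes != "same"])
    expect_setequal(tt$gene_id[tt$direct_target], want)
  }
})

test_that("lowering the RNA cutoff never removes a direct target", {
  set.seed(161)
  m <- matrix(rpois(200 * 4, 80) * runif(800, 0.3, 3), 200, 4,
              dimnames = list(sprintf("g%03d", 1:200),
                              c("WT_1", "WT_2", "KO_1", "KO_2")))
  cm <- count_matrix(m, norm_state = "CPM")
  bound <- sample(rownames(m), 80)
  prev <- NULL
  for (cut in c(2.0, 1.0, 0.7, 0.3)) {
    d <- classify_differential(cm, c("WT_1", "WT_2"), c("KO_1", "KO_2"), cut)
    tt <- call_direct_targets(bound, d)
    now <- tt$gene_id[tt$direct_target]
    if (!is.null(prev)) expect_true(all(prev %in% now))
    prev <- now
  }
})

test_that("the mechanism mapping matches the four-category taxonomy", {
  rna <- mk_rna(c("A", "B", "C", "D", "E", "F"),
                c("up", "up", "down", "down", "up", "up"))
  targets <- call_direct_targets(c("A", "B", "C", "D", "E"), rna)
  atac <- c(A = "up", B = "down", C = "up", D = "down", E = "same", F = "up")
  targets <- classify_mechanism(targets, atac)
  got <- setNames(targets$mechanism, targets$gene_id)
  expect_equal(unname(got["A"]), "repressed_via_closing")
  expect_equal(unname(got["B"]), "repressed_via_opening")
  expect_equal(unname(got["C"]), "activated_via_closing")
  expect_equal(unname(got["D"]), "activated_via_opening")
  expect_equal(unname(got["E"]), "unresolved")   # atac same
  expect_equal(unname(got["F"]), "unresolved")   # not bound
  # genes without any ATAC-classified peak stay none/unresolved
  targets2 <- classify_mechanism(call_direct_targets("A", rna), c(B = "up"))
  expect_equal(targets2$atac_class[targets2$gene_id == "A"], "none")
  expect_equal(targets2$mechanism[targets2$gene_id == "A"], "unresolved")
  # mechanisms + unresolved partition the table
  expect_true(all(targets$mechanism %in%
                    c("repressed_via_closing", "repressed_via_opening",
                      "activated_via_closing", "activated_via_opening",
                      "unresolved")))
})

test_that("gene-level ATAC class follows the strongest assigned peak", {
  assignments <- data.frame(name = c("p1", "p2", "p3", "p4"),
                            gene_id = c("gA", "gA", "gB", NA),
                            stringsAsFactors = FALSE)
  diff <- data.frame(feature_id = c("p1", "p2", "p3", "p4"),
                     log2fc = c(0.5, -2.0, 0.1, 3),
                     class = c("up", "down", "same", "up"),
                     stringsAsFactors = FALSE)
  cls <- summarize_gene_atac(assignments, diff)
  expect_equal(unname(cls["gA"]), "down")  # |−2| beats |0.5|
  expect_equal(unname(cls["gB"]), "same")
  expect_false("p4" %in% names(cls))       # unassigned peak ignored
})

test_that("cross-cell-type overlap keeps the set-size invariants", {
  ov <- cross_celltype_overlap(c("x", "y", "z"), c("y", "z", "w"))
  expect_equal(ov$summary$size, c(2, 1, 1))
  expect_setequal(ov$shared, c("y", "z"))
  ov <- cross_celltype_overlap(c("a", "b"), c("a", "b"))
  expect_equal(ov$summary$size, c(2, 0, 0))
  ov <- cross_celltype_overlap(c("a"), c("b"))
  expect_equal(ov$summary$size, c(0, 1, 1))
  set.seed(171)
  for (i in 1:10) {
    a <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(5:20, 1))
    ov <- cross_celltype_overlap(a, b)
    expect_equal(length(ov$shared) + length(ov$specific_a), length(unique(a)))
    expect_equal(length(ov$shared) + length(ov$specific_b), length(unique(b)))
  }
})

test_that("recovery scoring computes per-category precision and recall", {
  truth <- data.frame(
    gene_id = sprintf("g%02d", 1:10), bound = TRUE,
    rna_class = "up", atac_class = "up",
    mechanism = c(rep("repressed_via_closing", 4),
                  rep("activated_via_opening", 3), rep("unresolved", 3)),
    stringsAsFactors = FALSE
  )
  pred <- truth[, c("gene_id", "bound", "rna_class", "atac_class", "mechanism")]
  sc <- score_recovery(pred, truth)
  expect_true(all(sc$per_category$recall[sc$per_category$planted > 0] == 1))
  expect_true(all(sc$per_category$precision[sc$per_category$predicted > 0] == 1))

  # one miss, one false call
  pred$mechanism[1] <- "unresolved"
  pred$mechanism[10] <- "repressed_via_closing"
  sc <- score_recovery(pred, truth)
  row <- sc$per_category[sc$per_category$mechanism == "repressed_via_closing", ]
  expect_equal(row$recall, 3 / 4)
  expect_equal(row$precision, 3 / 4)

  # empty prediction: recall 0, precision undefined (NA)
  pred$mechanism <- "unresolved"
  sc <- score_recovery(pred, truth)
  row <- sc$per_category[sc$per_category$mechanism == "repressed_via_closing", ]
  expect_equal(row$recall, 0)
  expect_true(is.na(row$precision))

  bad <- pred; bad$gene_id[1] <- "not_in_truth"
  expect_error(score_recovery(bad, truth), "namespace")
})
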