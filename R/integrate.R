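# Gene-level tri-omic integration: direct targets are genes both bound
# (ChIP) and differentially expressed (RNA); the mechanism taxonomy further
# requires a differential-accessibility call (ATAC) at the gene and encodes
# what the remodeler's binding does at the locus.

MECHANISMS <- c("repressed_via_closing", "repressed_via_opening",
                "activated_via_closing", "activated_via_opening")

# (rna_class, atac_class) -> mechanism. "up" means higher in the knockout,
# so a bound gene that goes up while its chromatin opens was repressed by
# binding-mediated closing, and so on.
mechanism_for <- function(rna_class, atac_class) {
  ifelse(rna_class == "up" & atac_class == "up", "repressed_via_closing",
  ifelse(rna_class == "up" & atac_class == "down", "repressed_via_opening",
  ifelse(rna_class == "down" & atac_class == "up", "activated_via_closing",
  ifelse(rna_class == "down" & atac_class == "down", "activated_via_opening",
         "unresolved"))))
}

#' Call direct targets from binding and differential expression
#'
#' A direct target is a gene that is bound and whose RNA class is up or
#' down at the integration cutoff. The returned table covers the whole RNA
#' universe; `atac_class` starts as "none" and `mechanism` as "unresolved"
#' until [classify_mechanism()] fills them in.
#'
#' @param bound_genes character vector of bound gene ids
#' @param rna_diff result of [classify_differential()] on the RNA matrix
#'   (classified at the integration cutoff)
#' @return data.frame: gene_id, bound, rna_class, atac_class, mechanism,
#'   direct_target
#' @export
call_direct_targets <- function(bound_genes, rna_diff) {
  if (nrow(rna_diff) == 0) stop("empty RNA universe", call. = FALSE)
  stopifnot(all(c("feature_id", "class") %in% names(rna_diff)))
  data.frame(
    gene_id = rna_diff$feature_id,
    bound = rna_diff$feature_id %in% bound_genes,
    rna_class = rna_diff$class,
    atac_class = "none",
    mechanism = "unresolved",
    direct_target = rna_diff$feature_id %in% bound_genes &
      rna_diff$class %in% c("up", "down"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Fill in the four-category mechanism taxonomy
#'
#' For direct targets with an ATAC class of up or down, the mechanism is:
#' (rna up, atac up) repressed_via_closing; (rna up, atac down)
#' repressed_via_opening; (rna down, atac up) activated_via_closing;
#' (rna down, atac down) activated_via_opening. Genes without an
#' ATAC-classified peak keep atac_class "none" and stay unresolved.
#'
#' @param targets result of [call_direct_targets()]
#' @param atac_gene_classes named character vector (gene_id -> up/down/same),
#'   e.g. from [summarize_gene_atac()]
#' @return the target table with atac_class and mechanism filled
#' @export
classify_mechanism <- function(targets, atac_gene_classes) {
  stopifnot(is.data.frame(targets), all(c("gene_id", "bound", "rna_class") %in% names(targets)))
  cls <- atac_gene_classes[targets$gene_id]
  targets$atac_class <- ifelse(is.na(cls), "none", unname(cls))
  eligible <- targets$bound & targets$rna_class %in% c("up", "down") &
    targets$atac_class %in% c("up", "down")
  targets$mechanism <- "unresolved"
  targets$mechanism[eligible] <- mechanism_for(targets$rna_class[eligible],
                                               targets$atac_class[eligible])
  targets
}

#' Gene-level ATAC class from peak-level calls
#'
#' A gene may own several assigned peaks; its class is the class of the
#' assigned peak with the largest |log2FC| (ties: first peak in the table
#' after sorting by decreasing |log2FC| then peak name).
#'
#' @param assignments result of [assign_peaks_to_genes()] on the ATAC master
#'   peaks
#' @param atac_diff result of [classify_differential()] on the ATAC counts
#'   (feature ids = master peak names)
#' @return named character vector gene_id -> class
#' @export
summarize_gene_atac <- function(assignments, atac_diff) {
  merged <- merge(assignments[!is.na(assignments$gene_id),
                              c("name", "gene_id")],
                  atac_diff[, c("feature_id", "log2fc", "class")],
                  by.x = "name", by.y = "feature_id")
  if (nrow(merged) == 0) return(setNames(character(), character()))
  merged <- merged[order(-abs(merged$log2fc), merged$name), , drop = FALSE]
  best <- merged[!duplicated(merged$gene_id), , drop = FALSE]
  setNames(best$class, best$gene_id)
}

#' Shared/specific overlap of two gene sets
#'
#' @param a,b character vectors of gene ids in one namespace
#' @param label_a,label_b labels for reporting
#' @return list with sizes, the three member sets and an invariant-checked
#'   summary data.frame
#' @export
cross_celltype_overlap <- function(a, b, label_a = "a", label_b = "b") {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  shared <- intersect(a, b)
  spec_a <- setdiff(a, b)
  spec_b <- setdiff(b, a)
  list(
    shared = shared, specific_a = spec_a, specific_b = spec_b,
    summary = data.frame(
      set = c("shared", paste0("specific_", label_a), paste0("specific_", label_b)),
      size = c(length(shared), length(spec_a), length(spec_b)),
      stringsAsFactors = FALSE
    )
  )
}

#' Write the direct-target table as TSV
#' @param targets result of [classify_mechanism()]
#' @param path output path
#' @return invisibly, the path
#' @export
write_targets_tsv <- function(targets, path) {
  write.table(targets, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
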