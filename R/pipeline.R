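# Configuration and the one-command end-to-end run: simulate (or load) ->
# consensus -> master list -> counting -> differential -> annotate ->
# stratify -> integrate -> enrich -> recovery report. Every cutoff the
# analysis uses is configuration, never a constant in code.

pipeline_defaults <- function() {
  list(
    mode = "simulation",            # "simulation" or "files"
    seed = 7,
    sim = list(),                   # overrides passed to sim_config()
    cutoffs = list(
      atac_lfc = 0.4,               # accessibility tri-class cutoff
      rna_lfc = 1.0,                # headline expression cutoff (with FDR)
      rna_integration_lfc = 0.7,    # expression cutoff for target calling
      q_max = 0.05,
      use_fdr = FALSE
    ),
    overlap = list(consensus_min = 0.5, binding_min_bp = 1),
    regions = list(flank = 1500, bin = 50),
    annotation = list(tss_halfwidth = 500, max_tss_distance = 5000),
    enrichment = list(n_perm = 500, weight_p = 1, top_k = 10),
    inputs = list(
      chip_peaks = NULL,            # named list replicate -> BED path
      atac_peaks = NULL,            # list(WT = named list, KO = named list)
      fragments = NULL,             # named list sample -> BED path (WT_1, ...)
      rna_counts = NULL,            # counts TSV
      genes_bed12 = NULL,
      chrom_sizes = NULL,
      gene_sets_gmt = NULL
    )
  )
}

#' Build and validate a pipeline configuration
#'
#' Starts from the package defaults and merges overrides; unknown keys at
#' any level are an error (fail-closed), as are cutoffs <= 0 or a region
#' flank not divisible by the bin size.
#'
#' @param ... named overrides, e.g. `cutoffs = list(atac_lfc = 0.5)`
#' @return validated configuration list, class `pipeline_config`
#' @export
pipeline_config <- function(...) {
  cfg <- merge_config(pipeline_defaults(), list(...), path = "")
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

merge_config <- function(base, override, path) {
  if (length(override) == 0) return(base)
  if (is.null(names(override)) || any(!nzchar(names(override)))) {
    stop("config entries must be named (at '", path, "')", call. = FALSE)
  }
  unknown <- setdiff(names(override), names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) && nm != "sim" &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]],
                                 paste0(path, ".", nm))
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validate_pipeline_config <- function(cfg) {
  if (!cfg$mode %in% c("simulation", "files")) {
    stop("mode must be 'simulation' or 'files'", call. = FALSE)
  }
  cut <- cfg$cutoffs
  if (cut$atac_lfc <= 0 || cut$rna_lfc <= 0 || cut$rna_integration_lfc <= 0 ||
      cut$q_max <= 0) {
    stop("all cutoffs must be > 0", call. = FALSE)
  }
  if (cfg$regions$flank <= 0 || cfg$regions$bin <= 0 ||
      (2 * cfg$regions$flank) %% cfg$regions$bin != 0) {
    stop("region width (2 x flank) must be divisible by bin", call. = FALSE)
  }
  if (!is.null(cfg$sim) && length(cfg$sim)) {
    allowed <- names(formals(sim_config))
    unknown <- setdiff(names(cfg$sim), allowed)
    if (length(unknown)) {
      stop("unknown sim config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of overrides (same structure as
#'   [pipeline_config()] defaults)
#' @return validated `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# Load the file-mode inputs; all paths must exist before any stage runs.
load_pipeline_inputs <- function(cfg) {
  inp <- cfg$inputs
  need <- c("chip_peaks", "atac_peaks", "fragments", "rna_counts",
            "genes_bed12", "chrom_sizes")
  for (nm in need) {
    if (is.null(inp[[nm]])) stop("missing input: ", nm, call. = FALSE)
  }
  paths <- c(unlist(inp$chip_peaks), unlist(inp$atac_peaks),
             unlist(inp$fragments), inp$rna_counts, inp$genes_bed12,
             inp$chrom_sizes, inp$gene_sets_gmt)
  absent <- paths[!file.exists(paths)]
  if (length(absent)) {
    stop("input file(s) not found: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  genome <- read_chrom_sizes(inp$chrom_sizes)
  annotation <- read_bed12_genes(inp$genes_bed12)
  read_reps <- function(paths) {
    ids <- names(paths) %||% paste0("rep", seq_along(paths))
    setNames(lapply(seq_along(paths), function(i) {
      read_bed(paths[[i]], replicate_id = ids[i])
    }), ids)
  }
  list(
    genome = genome,
    annotation = annotation,
    chip_replicate_peaks = read_reps(inp$chip_peaks),
    atac_replicate_peaks = lapply(inp$atac_peaks, read_reps),
    fragments = lapply(inp$fragments, read_bed),
    rna = read_counts_tsv(inp$rna_counts),
    gene_sets = if (!is.null(inp$gene_sets_gmt)) read_gmt(inp$gene_sets_gmt) else NULL,
    truth = NULL,
    hashes = as.list(tools::md5sum(paths))
  )
}

# Simulation-mode inputs from the generator.
sim_pipeline_inputs <- function(cfg) {
  sim_cfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  exp <- simulate_experiment(sim_cfg)
  list(
    genome = exp$genome,
    annotation = exp$annotation,
    chip_replicate_peaks = exp$chip$replicate_peaks,
    atac_replicate_peaks = exp$atac$replicate_peaks,
    fragments = exp$atac$fragments,
    rna = exp$rna,
    gene_sets = exp$gene_sets,
    truth = exp$truth,
    hashes = NULL,
    experiment = exp
  )
}

#' Run the tri-omic pipeline end to end
#'
#' Executes consensus aggregation, master-list counting and tri-class
#' differential calls for ATAC, feature annotation and gene assignment for
#' ChIP, binding stratification with paired coverage profiles, RNA
#' differential calls at the headline and integration cutoffs, direct-target
#' calling with the mechanism taxonomy, and gene-set enrichment. In
#' simulation mode the planted truth is scored and reported. Every
#' intermediate is written as plain text into `out_dir` together with a JSON
#' manifest of the parameters actually used; a rerun with the same
#' configuration reproduces the TSV outputs byte for byte.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list with every stage result (master peaks,
#'   differential tables, stratification, targets, enrichment, recovery)
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("chromtriad_run_")) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- if (config$mode == "simulation") sim_pipeline_inputs(config)
            else load_pipeline_inputs(config)
  genome <- inputs$genome
  annotation <- inputs$annotation

  # --- consensus and master list -------------------------------------------
  chip_consensus <- aggregate_replicates(inputs$chip_replicate_peaks,
                                         min_overlap = config$overlap$consensus_min,
                                         sample_id = "chip")
  atac_consensus <- lapply(names(inputs$atac_replicate_peaks), function(g) {
    aggregate_replicates(inputs$atac_replicate_peaks[[g]],
                         min_overlap = config$overlap$consensus_min,
                         sample_id = g)
  })
  names(atac_consensus) <- names(inputs$atac_replicate_peaks)
  master <- union_peak_lists(atac_consensus)

  # --- counting and ATAC differential --------------------------------------
  atac_counts <- count_fragments_in_peaks(inputs$fragments, master)
  atac_tpm <- normalize_counts(atac_counts, "TPM")
  samples <- colnames(atac_tpm$counts)
  wt <- grep("^WT", samples, value = TRUE)
  ko <- grep("^KO", samples, value = TRUE)
  if (length(wt) == 0 || length(ko) == 0) {
    stop("fragment samples must be named WT_* and KO_*", call. = FALSE)
  }
  atac_diff <- classify_differential(atac_tpm, wt, ko,
                                     lfc_cutoff = config$cutoffs$atac_lfc)
  qc <- lapply(inputs$fragments, fragment_size_qc)

  # --- annotation -----------------------------------------------------------
  fmap <- build_feature_map(annotation, genome,
                            tss_halfwidth = config$annotation$tss_halfwidth)
  chip_enrichment <- region_proportion_enrichment(chip_consensus, fmap)
  chip_assign <- assign_peaks_to_genes(chip_consensus, annotation,
                                       max_tss_distance = config$annotation$max_tss_distance)
  bound_genes <- sort(unique(chip_assign$gene_id[!is.na(chip_assign$gene_id)]))
  atac_assign <- assign_peaks_to_genes(master, annotation,
                                       max_tss_distance = config$annotation$max_tss_distance)
  atac_gene_classes <- summarize_gene_atac(atac_assign, atac_diff)

  # --- stratification and coverage -----------------------------------------
  master_classed <- master
  master_classed$class <- atac_diff$class[match(master$name, atac_diff$feature_id)]
  strat <- stratify_by_binding(master_classed, chip_consensus,
                               min_bp = config$overlap$binding_min_bp)
  wt_frags <- do.call(rbind, inputs$fragments[wt])
  ko_frags <- do.call(rbind, inputs$fragments[ko])
  profiles <- list()
  for (cell in names(strat$cells)) {
    peaks <- strat$cells[[cell]]
    if (nrow(peaks) == 0) next
    regions <- suppressWarnings(make_regions(peaks, flank = config$regions$flank,
                                             genome = genome))
    if (nrow(regions) == 0) next
    pair <- coverage_pair(wt_frags, ko_frags, regions,
                          bin_size = config$regions$bin, norm = "per_million")
    profiles[[cell]] <- list(regions = regions,
                             wt = pair$a, ko = pair$b,
                             profile_wt = region_profile(pair$a),
                             profile_ko = region_profile(pair$b))
  }

  # --- RNA differential and integration ------------------------------------
  rna_cm <- inputs$rna
  if (is.null(rna_cm$feature_lengths)) {
    # exonic length from the annotation (file-mode counts carry no lengths)
    ex <- annotation$exons
    exlen <- tapply(ex$end - ex$start, ex$gene_id, sum)
    rna_cm <- count_matrix(rna_cm$counts,
                           feature_lengths = setNames(as.numeric(exlen), names(exlen)))
  }
  rna_tpm <- normalize_counts(rna_cm, "TPM")
  rna_wt <- grep("^WT", colnames(rna_tpm$counts), value = TRUE)
  rna_ko <- grep("^KO", colnames(rna_tpm$counts), value = TRUE)
  rna_diff <- classify_differential(rna_tpm, rna_wt, rna_ko,
                                    lfc_cutoff = config$cutoffs$rna_lfc,
                                    use_fdr = config$cutoffs$use_fdr,
                                    q_max = config$cutoffs$q_max)
  rna_int <- classify_differential(rna_tpm, rna_wt, rna_ko,
                                   lfc_cutoff = config$cutoffs$rna_integration_lfc)
  targets <- call_direct_targets(bound_genes, rna_int)
  targets <- classify_mechanism(targets, atac_gene_classes)

  # --- enrichment -----------------------------------------------------------
  enrichment <- NULL
  if (!is.null(inputs$gene_sets)) {
    ranked <- data.frame(gene = rna_diff$feature_id, score = rna_diff$log2fc)
    pre <- preranked_collection(ranked, inputs$gene_sets,
                                weight_p = config$enrichment$weight_p,
                                n_perm = config$enrichment$n_perm,
                                seed = config$seed + 1000L)
    direct <- targets$gene_id[targets$direct_target]
    ora <- ora_collection(direct, inputs$gene_sets, targets$gene_id)
    enrichment <- list(preranked = pre,
                       preranked_top = top_enriched(pre, config$enrichment$top_k),
                       ora = ora,
                       ora_top = top_enriched(ora, config$enrichment$top_k))
  }

  recovery <- if (!is.null(inputs$truth)) score_recovery(targets, inputs$truth)

  # --- outputs --------------------------------------------------------------
  res <- list(
    config = config,
    genome = genome, annotation = annotation,
    chip_consensus = chip_consensus, atac_consensus = atac_consensus,
    master = master, atac_counts = atac_counts, atac_diff = atac_diff,
    fragment_qc = qc,
    feature_map = fmap, chip_enrichment = chip_enrichment,
    bound_genes = bound_genes, atac_gene_classes = atac_gene_classes,
    stratification = strat, profiles = profiles,
    rna_diff = rna_diff, rna_integration_diff = rna_int,
    targets = targets, enrichment = enrichment,
    recovery = recovery,
    truth = inputs$truth
  )
  write_pipeline_outputs(res, out_dir, inputs$hashes)
  res$out_dir <- out_dir
  invisible(res)
}

write_pipeline_outputs <- function(res, out_dir, hashes) {
  p <- function(...) file.path(out_dir, ...)
  write_bed(res$chip_consensus, p("chip_consensus.bed"), support = TRUE)
  master_out <- res$master
  master_out$score <- 0
  write_bed(master_out, p("atac_master_peaks.bed"))
  write_counts_tsv(res$atac_counts, p("atac_counts.tsv"))
  write_differential_tsv(res$atac_diff, p("atac_differential.tsv"))
  write_differential_tsv(res$rna_diff, p("rna_differential.tsv"))
  write_differential_tsv(res$rna_integration_diff, p("rna_integration_differential.tsv"))
  write.table(res$chip_enrichment, p("chip_feature_enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (cell in names(res$stratification$cells)) {
    df <- res$stratification$cells[[cell]]
    if (nrow(df)) write_bed(df, p(paste0("stratified_", cell, ".bed")))
  }
  prof <- do.call(rbind, lapply(names(res$profiles), function(cell) {
    pr <- res$profiles[[cell]]
    data.frame(cell = cell,
               bin = seq_along(pr$profile_wt),
               wt_mean = pr$profile_wt, ko_mean = pr$profile_ko,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(prof)) {
    write.table(prof, p("coverage_profiles.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  qc_df <- do.call(rbind, lapply(names(res$fragment_qc), function(s) {
    q <- res$fragment_qc[[s]]
    data.frame(sample = s, fraction_below_100bp = q$fraction_below_100bp,
               modal_size = q$modal_size, periodicity_flag = q$periodicity_flag,
               stringsAsFactors = FALSE)
  }))
  write.table(qc_df, p("fragment_qc.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_targets_tsv(res$targets, p("direct_targets.tsv"))
  if (!is.null(res$enrichment)) {
    write.table(res$enrichment$preranked, p("enrichment_preranked.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$enrichment$ora, p("enrichment_ora.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$recovery)) {
    write.table(res$recovery$per_category, p("recovery_per_category.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package = "chromtriad",
    version = as.character(utils::packageVersion("chromtriad")),
    parameters = unclass(res$config),
    input_hashes = hashes
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(out_dir)
}
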