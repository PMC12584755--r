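# End-to-end orchestration: configuration, validation, and a run_pipeline()
# driver that chains simulation/ingest, preprocessing, activity
# designation, BACI dynamics, enrichment, and community statistics, writing
# TSV outputs and a JSON manifest.

#' Pipeline configuration
#'
#' Collects every tunable stage parameter with the analysis defaults:
#' rarefaction depth 12000 reads, activity ratio threshold 1, consistency
#' cut 0.5, FDR 0.05, minimum log2 fold change 1, pseudo-count 0.5.
#'
#' @param dna_path,cdna_path,meta_path,taxonomy_path TSV inputs; leave
#'   `NULL` with `simulate = TRUE` to run on simulated data.
#' @param simulate simulate inputs via [simulate_mesocosm()].
#' @param spec [design_spec()] used when simulating.
#' @param rarefaction_depth reads per library after subsampling.
#' @param ratio_threshold activity threshold on the rRNA:rRNA-gene ratio.
#' @param c_min consistency threshold for reactivation/persistence.
#' @param fdr,lfc_min,epsilon,alpha_min enrichment parameters.
#' @param contaminant_alpha prevalence-screen threshold.
#' @param n_perm PERMANOVA permutations.
#' @param seed master RNG seed.
#' @param out_dir output directory.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(dna_path = NULL, cdna_path = NULL,
                            meta_path = NULL, taxonomy_path = NULL,
                            simulate = is.null(dna_path),
                            spec = design_spec(),
                            rarefaction_depth = 12000,
                            ratio_threshold = 1.0,
                            c_min = 0.5, fdr = 0.05, lfc_min = 1.0,
                            epsilon = 0.5, alpha_min = 1e-8,
                            contaminant_alpha = 0.05,
                            n_perm = 999, seed = 1L,
                            out_dir = tempfile("phantax_run_")) {
  structure(list(dna_path = dna_path, cdna_path = cdna_path,
                 meta_path = meta_path, taxonomy_path = taxonomy_path,
                 simulate = simulate, spec = spec,
                 rarefaction_depth = rarefaction_depth,
                 ratio_threshold = ratio_threshold, c_min = c_min,
                 fdr = fdr, lfc_min = lfc_min, epsilon = epsilon,
                 alpha_min = alpha_min,
                 contaminant_alpha = contaminant_alpha,
                 n_perm = n_perm, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Lists every constraint violation with its key path. Unknown keys yield
#' warnings, not violations.
#'
#' @param config a [pipeline_config()] (or plain named list).
#' @return character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(config), c(known, "spec"))
  if (length(extra))
    warning(paste("unknown config keys ignored:", paste(extra, collapse = ", ")))
  chk(config$rarefaction_depth >= 1,
      "rarefaction_depth: rarefaction depth must be >= 1")
  chk(config$ratio_threshold > 0, "ratio_threshold: must be > 0")
  chk(config$c_min >= 0 && config$c_min <= 1, "c_min: must be in [0, 1]")
  chk(config$fdr > 0 && config$fdr <= 1, "fdr: must be in (0, 1]")
  chk(config$lfc_min >= 0, "lfc_min: must be >= 0")
  chk(config$epsilon > 0, "epsilon: must be > 0")
  chk(config$n_perm >= 1, "n_perm: must be >= 1")
  if (!isTRUE(config$simulate)) {
    for (key in c("dna_path", "cdna_path", "meta_path"))
      chk(!is.null(config[[key]]) && file.exists(config[[key]]),
          sprintf("%s: input file must exist when simulate = FALSE", key))
  }
  v
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, pairing, rarefaction, contaminant screen,
#' phantom adjustment, ratio classification, active-community
#' construction, BACI transition report, day-1 enrichment contrasts per
#' soil x treatment, diversity and PERMANOVA reports, and the long-format
#' activity table. Every stage output is written as TSV in
#' `config$out_dir`, and a JSON manifest records parameters, seeds, and
#' per-stage row counts.
#'
#' @param config a valid [pipeline_config()].
#' @return (invisibly) the output directory; side effect: files on disk.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  violations <- validate_config(config)
  if (length(violations))
    stop_phantax(paste("invalid configuration:\n",
                       paste(violations, collapse = "\n ")),
                 "validation_error")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message(sprintf(...))
  manifest <- list(parameters = config[!vapply(config, is.list, TRUE)],
                   stages = list())

  # --- ingest or simulate ------------------------------------------------
  if (config$simulate) {
    sim <- simulate_mesocosm(config$spec)
    dna <- sim$dna; cdna <- sim$cdna; meta <- sim$meta
    taxonomy <- NULL
    write_tsv(sim$truth, file.path(config$out_dir, "ground_truth.tsv"))
  } else {
    dna <- read_count_table(config$dna_path)
    cdna <- read_count_table(config$cdna_path)
    meta <- read_sample_metadata(config$meta_path)
    taxonomy <- if (!is.null(config$taxonomy_path))
      read_taxonomy(config$taxonomy_path) else NULL
  }
  manifest$stages$ingest <- list(n_taxa = nrow(dna),
                                 n_dna = ncol(dna), n_cdna = ncol(cdna))

  # --- contaminant and organelle filtering -------------------------------
  both <- cbind(dna, cdna)
  if (any(meta$is_negative_control)) {
    screen <- flag_contaminants(both, meta, config$contaminant_alpha)
    flagged <- screen$taxon_id[screen$flagged]
    write_tsv(screen, file.path(config$out_dir, "contaminant_screen.tsv"))
  } else flagged <- character()
  if (!is.null(taxonomy)) {
    filt <- filter_taxonomy(both, taxonomy)
    flagged <- union(flagged, attr(filt, "removed"))
  }
  dna <- dna[!rownames(dna) %in% flagged, , drop = FALSE]
  cdna <- cdna[!rownames(cdna) %in% flagged, , drop = FALSE]
  log_msg("filtering: removed %d taxa", length(flagged))
  manifest$stages$filtering <- list(n_removed = length(flagged))

  # --- rarefy both tables separately to the same depth -------------------
  dna_r <- rarefy(dna, config$rarefaction_depth, seed = config$seed)
  cdna_r <- rarefy(cdna, config$rarefaction_depth, seed = config$seed + 1L)
  dropped <- c(attr(dna_r, "dropped"), attr(cdna_r, "dropped"))
  log_msg("rarefaction: dropped %d libraries below depth %d",
          length(dropped), config$rarefaction_depth)
  manifest$stages$rarefaction <- list(depth = config$rarefaction_depth,
                                      n_dropped = length(dropped))

  # --- pair; a pair is excluded if either library failed depth -----------
  paired <- pair_libraries(dna_r, cdna_r, meta)
  write_count_table(paired$dna, file.path(config$out_dir, "paired_dna.tsv"))
  write_count_table(paired$cdna, file.path(config$out_dir, "paired_cdna.tsv"))
  manifest$stages$pairing <- list(n_pairs = ncol(paired$dna),
                                  n_unpaired = length(paired$unpaired))

  # --- activity designation ---------------------------------------------
  adj <- phantom_adjust(paired$dna, paired$cdna)
  log_msg("phantom adjustment: %d cells set to DNA = 1", attr(adj, "n_adjusted"))
  calls <- classify_activity(adj, paired$cdna, config$ratio_threshold)
  util <- calls$ratio; util[is.na(util)] <- ""
  write_tsv(data.frame(taxon_id = rownames(calls$ratio), util,
                       check.names = FALSE),
            file.path(config$out_dir, "ratios.tsv"))
  write_tsv(data.frame(taxon_id = rownames(calls$state), calls$state,
                       check.names = FALSE),
            file.path(config$out_dir, "states.tsv"))
  active <- active_community(paired$dna, calls)
  write_count_table(active, file.path(config$out_dir, "active_community.tsv"))
  manifest$stages$activity <- list(
    n_phantom = attr(adj, "n_adjusted"),
    n_active_taxa = nrow(active),
    threshold = config$ratio_threshold)

  # --- enrichment contrasts: day1 vs water-acclimated baseline -----------
  pm <- meta[meta$nucleic_acid == "DNA" & meta$pair_id %in% colnames(paired$dna), ]
  contrasts <- list()
  for (soil in unique(pm$soil)) {
    base_ids <- pm$pair_id[pm$soil == soil & pm$treatment == "none" &
                             pm$timepoint == "water_acclimated"]
    if (!length(base_ids)) next
    for (trt in setdiff(unique(pm$treatment[pm$soil == soil]), "none")) {
      d1 <- pm$pair_id[pm$soil == soil & pm$treatment == trt &
                         pm$timepoint == "day1"]
      if (!length(d1)) next
      res <- nb_wald_contrast(paired$dna, groupA = base_ids, groupB = d1,
                              epsilon = config$epsilon,
                              alpha_min = config$alpha_min)
      contrasts[[soil]][[trt]] <- res
      write_tsv(res, file.path(config$out_dir,
                               sprintf("contrast_%s_%s_day1.tsv", soil, trt)))
    }
  }
  manifest$stages$enrichment <- list(n_contrasts =
                                       sum(lengths(contrasts)))

  # --- BACI dynamics ------------------------------------------------------
  hormones <- intersect(unique(pm$treatment), c("ABA", "SA"))
  transitions <- baci_transitions(calls, meta, active, contrasts,
                                  c_min = config$c_min, fdr = config$fdr,
                                  lfc_min = config$lfc_min,
                                  hormones = hormones)
  write_tsv(transitions, file.path(config$out_dir, "transitions.tsv"))
  if (!length(hormones))
    warning("no hormone conditions configured; specificity table is empty")
  long <- activity_long_table(calls, meta, active)
  write_tsv(long, file.path(config$out_dir, "activity_long.tsv"))
  manifest$stages$dynamics <- list(
    n_records = nrow(transitions),
    n_reactivated = sum(transitions$reactivated),
    n_persistent = sum(transitions$persistent),
    n_specific = sum(transitions$treatment_specific, na.rm = TRUE))

  # --- community statistics on the active community ----------------------
  div <- data.frame(
    pair_id = colnames(active),
    richness = apply(active, 2, richness),
    inverse_simpson = apply(active, 2, function(x)
      if (sum(x) > 0) inverse_simpson(x) else NA_real_),
    row.names = NULL)
  write_tsv(div, file.path(config$out_dir, "alpha_diversity.tsv"))
  keep <- colSums(active) > 0
  act <- active[, keep, drop = FALSE]
  grp <- pm$treatment[match(colnames(act), pm$pair_id)]
  stats_tab <- NULL
  if (length(unique(grp)) >= 2) {
    bc <- bray_curtis(act)
    pmv <- permanova(bc, grp, n_perm = config$n_perm,
                     seed = config$seed + 2L)
    stats_tab <- data.frame(term = "treatment", df = pmv$df_between,
                            R2 = pmv$R2, pseudo_F = pmv$pseudo_F, p = pmv$p)
    write_tsv(stats_tab, file.path(config$out_dir, "permanova.tsv"))
  }
  manifest$stages$community_stats <- list(n_samples = ncol(act))

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_msg("pipeline complete: %s", config$out_dir)
  invisible(config$out_dir)
}
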