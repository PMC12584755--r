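# Condition-level activity dynamics: replicate-consistency scores,
# reactivation against the water-acclimated baseline, persistence over the
# time series, and treatment specificity.

# metadata rows (one per pair) for a soil/treatment/timepoint stratum
pair_meta <- function(calls, meta) {
  m <- meta[meta$nucleic_acid == "DNA", ]
  m <- m[match(colnames(calls$state), m$pair_id), ]
  if (anyNA(m$pair_id))
    stop_phantax("metadata does not cover every sample pair in the calls",
                 "validation_error")
  m
}

condition_pairs <- function(pm, soil, treatment, timepoint) {
  pm$pair_id[pm$soil == soil & pm$treatment == treatment &
               pm$timepoint == timepoint]
}

#' Replicate-consistency score
#'
#' Fraction of replicate sample pairs (mesocosm x technical) of a
#' soil/treatment/timepoint stratum in which a taxon is classified ACTIVE:
#' 1 denotes activity in all replicates, 0.5 in half. The denominator is
#' the number of pairs with surviving libraries, not the nominal count.
#'
#' @param calls an `activity_calls` object.
#' @param meta library metadata covering the calls' pairs.
#' @param taxon taxon ID.
#' @param soil,treatment,timepoint the condition key.
#' @return fraction in `[0, 1]`.
#' @export
consistency_score <- function(calls, meta, taxon, soil, treatment, timepoint) {
  pm <- pair_meta(calls, meta)
  ids <- condition_pairs(pm, soil, treatment, timepoint)
  if (!length(ids))
    stop_phantax(sprintf("no replicates for %s/%s/%s", soil, treatment,
                         timepoint), "missing_condition")
  if (!taxon %in% rownames(calls$state))
    stop_phantax(paste("unknown taxon:", taxon), "validation_error")
  mean(calls$state[taxon, ids] == "A")
}

# all-taxon consistency vector for one condition (internal, vectorized)
consistency_all <- function(calls, pm, soil, treatment, timepoint) {
  ids <- condition_pairs(pm, soil, treatment, timepoint)
  if (!length(ids)) return(NULL)
  rowMeans(calls$state[, ids, drop = FALSE] == "A")
}

#' Classify reactivation from the water-acclimated baseline
#'
#' A taxon is reactivated when it was never active in any water-acclimated
#' baseline replicate of the same soil (INACTIVE or NOT_DETECTED in every
#' replicate) and is active at day 1 of the treatment with consistency at
#' least `c_min`.
#'
#' @param calls `activity_calls`.
#' @param meta library metadata.
#' @param taxon taxon ID.
#' @param soil,treatment condition of interest.
#' @param c_min minimum day-1 consistency (default 0.5).
#' @param baseline_timepoint,baseline_treatment the pre-treatment baseline
#'   condition (water-acclimated, treatment "none").
#' @return logical.
#' @export
classify_reactivation <- function(calls, meta, taxon, soil, treatment,
                                  c_min = 0.5,
                                  baseline_timepoint = "water_acclimated",
                                  baseline_treatment = "none") {
  pm <- pair_meta(calls, meta)
  base_ids <- condition_pairs(pm, soil, baseline_treatment, baseline_timepoint)
  if (!length(base_ids))
    stop_phantax(sprintf("baseline %s/%s/%s absent", soil, baseline_treatment,
                         baseline_timepoint), "missing_baseline")
  base_cons <- mean(calls$state[taxon, base_ids] == "A")
  day1 <- consistency_score(calls, meta, taxon, soil, treatment, "day1")
  base_cons == 0 && day1 >= c_min
}

#' Classify persistence over the treatment time series
#'
#' A taxon persists when its activity consistency is at least `c_min` at
#' day 1, day 7 and day 14 of the treatment.
#'
#' @inheritParams classify_reactivation
#' @param timepoints the series that must all be active.
#' @return logical.
#' @export
classify_persistence <- function(calls, meta, taxon, soil, treatment,
                                 c_min = 0.5,
                                 timepoints = c("day1", "day7", "day14")) {
  pm <- pair_meta(calls, meta)
  missing <- timepoints[!vapply(timepoints, function(tp)
    length(condition_pairs(pm, soil, treatment, tp)) > 0, TRUE)]
  if (length(missing))
    stop_phantax(paste("missing timepoints:", paste(missing, collapse = ", ")),
                 "partial_series")
  all(vapply(timepoints, function(tp)
    consistency_score(calls, meta, taxon, soil, treatment, tp) >= c_min, TRUE))
}

#' Treatment-specific enrichment
#'
#' A taxon responds specifically to the hormone when its day-1 vs baseline
#' contrast is enriched (adjusted p at most `fdr` and log2 fold change at
#' least `lfc_min`) while neither the methanol-carrier nor the water
#' control contrast meets both criteria.
#'
#' @param hormone_result,methanol_result,water_result single-taxon rows
#'   (lists or one-row data.frames) with `log2fc` and `padj`.
#' @param fdr adjusted-p threshold (default 0.05).
#' @param lfc_min log2 fold-change threshold (default 1, a log twofold
#'   increase).
#' @return logical.
#' @export
classify_treatment_specificity <- function(hormone_result, methanol_result,
                                           water_result, fdr = 0.05,
                                           lfc_min = 1.0) {
  enr <- function(r) {
    if (is.null(r) || anyNA(c(r$log2fc, r$padj)))
      stop_phantax("incomplete contrast evidence", "incomplete_evidence")
    r$padj <= fdr && r$log2fc >= lfc_min
  }
  enr(hormone_result) && !enr(methanol_result) && !enr(water_result)
}

#' Most abundant active taxa in a stratum
#'
#' Top `n` taxa by summed active-community DNA counts within a
#' soil/treatment stratum, ties broken deterministically by taxon ID.
#'
#' @param active_table active-community count matrix (columns are pair
#'   IDs).
#' @param meta library metadata.
#' @param soil,treatment stratum key.
#' @param n number of taxa (default 50).
#' @return character vector of taxon IDs (all taxa, with a message, when
#'   fewer than `n` are present).
#' @export
select_top_active <- function(active_table, meta, soil, treatment, n = 50L) {
  pm <- meta[meta$nucleic_acid == "DNA", ]
  ids <- pm$pair_id[pm$soil == soil & pm$treatment == treatment]
  ids <- intersect(colnames(active_table), ids)
  if (!length(ids))
    stop_phantax(sprintf("no samples for stratum %s/%s", soil, treatment),
                 "missing_condition")
  tot <- rowSums(active_table[, ids, drop = FALSE])
  ord <- order(-tot, rownames(active_table))
  if (n >= length(ord)) {
    message(sprintf("only %d taxa present; returning all", length(ord)))
    return(rownames(active_table)[ord])
  }
  rownames(active_table)[ord][seq_len(n)]
}

#' Full BACI transition report
#'
#' For every taxon x soil x treatment (excluding the baseline "none"
#' stratum), computes baseline/day consistencies, the reactivation and
#' persistence flags, and — when `contrasts` are supplied — treatment
#' specificity. Mean max-standardized active relative abundances per
#' timepoint are attached for display.
#'
#' @param calls `activity_calls`.
#' @param meta library metadata.
#' @param active_table active-community matrix from [active_community()].
#' @param contrasts optional named list: `contrasts[[soil]][[treatment]]` a
#'   [nb_wald_contrast()] result (day1 vs baseline) for each treatment
#'   including the `methanol` and `water` controls.
#' @param c_min consistency threshold (default 0.5).
#' @param fdr,lfc_min enrichment thresholds for specificity.
#' @param hormones treatments eligible for specificity classification.
#' @return data.frame of transition records.
#' @export
baci_transitions <- function(calls, meta, active_table = NULL,
                             contrasts = NULL, c_min = 0.5, fdr = 0.05,
                             lfc_min = 1.0, hormones = c("ABA", "SA")) {
  pm <- pair_meta(calls, meta)
  taxa <- rownames(calls$state)
  strata <- unique(pm[pm$treatment != "none", c("soil", "treatment")])
  tps <- c("day1", "day7", "day14")
  rel <- if (!is.null(active_table)) max_standardize(active_table) else NULL
  recs <- list()
  for (s in seq_len(nrow(strata))) {
    soil <- strata$soil[s]; trt <- strata$treatment[s]
    base <- consistency_all(calls, pm, soil, "none", "water_acclimated")
    cons <- lapply(tps, function(tp) consistency_all(calls, pm, soil, trt, tp))
    names(cons) <- tps
    if (is.null(base) || any(vapply(cons, is.null, TRUE))) next
    reactivated <- base == 0 & cons$day1 >= c_min
    persistent <- cons$day1 >= c_min & cons$day7 >= c_min & cons$day14 >= c_min
    specific <- rep(NA, length(taxa))
    if (!is.null(contrasts) && trt %in% hormones) {
      ch <- contrasts[[soil]][[trt]]
      cm <- contrasts[[soil]][["methanol"]]
      cw <- contrasts[[soil]][["water"]]
      if (!is.null(ch) && !is.null(cm) && !is.null(cw)) {
        hit <- function(cr) {
          i <- match(taxa, cr$taxon_id)
          !is.na(cr$padj[i]) & cr$padj[i] <= fdr &
            !is.na(cr$log2fc[i]) & cr$log2fc[i] >= lfc_min
        }
        specific <- hit(ch) & !hit(cm) & !hit(cw)
      }
    }
    mean_rel <- function(tp) {
      if (is.null(rel)) return(rep(NA_real_, length(taxa)))
      ids <- intersect(condition_pairs(pm, soil, trt, tp), colnames(rel))
      out <- rep(0, length(taxa)); names(out) <- taxa
      if (length(ids)) {
        m <- rowMeans(rel[, ids, drop = FALSE])
        out[names(m)] <- m
      }
      out
    }
    recs[[length(recs) + 1L]] <- data.frame(
      taxon_id = taxa, soil = soil, treatment = trt,
      baseline_consistency = base,
      day1_consistency = cons$day1, day7_consistency = cons$day7,
      day14_consistency = cons$day14,
      reactivated = reactivated, persistent = persistent,
      treatment_specific = specific,
      mean_relabund_day1 = mean_rel("day1"),
      mean_relabund_day7 = mean_rel("day7"),
      mean_relabund_day14 = mean_rel("day14"),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!length(recs))
    stop_phantax("no treatment strata with complete time series",
                 "partial_series")
  do.call(rbind, recs)
}

#' Long-format activity table for bubble displays
#'
#' One row per taxon x condition x timepoint with the max-standardized
#' mean active relative abundance, the consistency score, and the state
#' symbol ("A" active, "I" inactive i.e. detected in DNA only, "+" not
#' detected in either library).
#'
#' @inheritParams baci_transitions
#' @param top_n taxa per soil/treatment stratum (default 50).
#' @return long data.frame suitable for plotting.
#' @export
activity_long_table <- function(calls, meta, active_table, top_n = 50L) {
  pm <- pair_meta(calls, meta)
  rel <- max_standardize(active_table)
  strata <- unique(pm[pm$treatment != "none", c("soil", "treatment")])
  out <- list()
  for (s in seq_len(nrow(strata))) {
    soil <- strata$soil[s]; trt <- strata$treatment[s]
    taxa <- select_top_active(active_table, meta, soil, trt, n = top_n)
    tps <- unique(pm$timepoint[pm$soil == soil & pm$treatment == trt])
    for (tp in tps) {
      ids <- condition_pairs(pm, soil, trt, tp)
      st <- calls$state[taxa, ids, drop = FALSE]
      symbol <- apply(st, 1, function(x) {
        if (any(x == "A")) "A" else if (all(x == "+")) "+" else "I"
      })
      relm <- rel[taxa, intersect(ids, colnames(rel)), drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        taxon_id = taxa, soil = soil, treatment = trt, timepoint = tp,
        relabund = rowMeans(relm),
        consistency = rowMeans(st == "A"),
        state = symbol, row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
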