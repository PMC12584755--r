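# Paired DNA/cDNA community simulator with known ground-truth activity.
#
# The latent model: each taxon carries a fixed log relative DNA abundance
# and a dormancy probability; a responder taxon is forced inactive at the
# water-acclimated baseline and reactivates at day1 only under its
# responder condition, with its DNA abundance multiplied by a growth
# factor while active. Activity states are drawn per taxon x mesocosm x
# timepoint (technical replicates and the DNA/cDNA pair share the
# biological state); the rRNA:rRNA-gene ratio of each (taxon, pair) is
# drawn from a lognormal whose central value is >= 1 for active and < 1
# for inactive states. Sequencing is multinomial per library at a
# lognormal library size.

#' Generate a taxon profile table
#'
#' @param n_taxa number of taxa.
#' @param n_responders number of hormone responder taxa; assigned
#'   round-robin to `responder_conditions`.
#' @param responder_conditions condition labels responders react to.
#' @param prop_persistent fraction of responders that stay active through
#'   the series (the rest revert to inactive after day1).
#' @param dormant_fraction_baseline baseline probability of inactivity for
#'   non-responder taxa.
#' @param growth_multiplier factor (>= 1) applied to a responder's DNA
#'   abundance while reactivated.
#' @param active_ratio,inactive_ratio central (geometric-mean) rRNA:rRNA-gene
#'   ratios for active (>= 1) and inactive (< 1) states.
#' @param ratio_logsd lognormal sd (log scale) of latent ratios.
#' @param abundance_logsd sd of base log abundances across taxa.
#' @param seed RNG seed.
#' @return data.frame with one row per taxon.
#' @export
taxon_profiles <- function(n_taxa = 200L,
                           n_responders = 10L,
                           responder_conditions = c("ABA", "SA"),
                           prop_persistent = 0.5,
                           dormant_fraction_baseline = 0.5,
                           growth_multiplier = 8,
                           active_ratio = 4,
                           inactive_ratio = 0.25,
                           ratio_logsd = 0.35,
                           abundance_logsd = 1,
                           seed = 1L) {
  if (active_ratio < 1 || inactive_ratio >= 1)
    stop_phantax("active_ratio must be >= 1 and inactive_ratio < 1",
                 "configuration_error")
  if (growth_multiplier < 1)
    stop_phantax("growth_multiplier must be >= 1", "configuration_error")
  if (n_responders > n_taxa)
    stop_phantax("n_responders cannot exceed n_taxa", "configuration_error")
  if (!length(responder_conditions)) n_responders <- 0L
  set.seed(seed)
  id <- sprintf("OTU%04d", seq_len(n_taxa))
  resp <- rep(NA_character_, n_taxa)
  pers <- rep(FALSE, n_taxa)
  if (n_responders > 0) {
    idx <- seq_len(n_responders)
    resp[idx] <- rep_len(responder_conditions, n_responders)
    pers[idx] <- seq_len(n_responders) <= round(prop_persistent * n_responders)
  }
  data.frame(
    taxon_id = id,
    base_log_abundance = stats::rnorm(n_taxa, 0, abundance_logsd),
    dormant_fraction_baseline = dormant_fraction_baseline,
    responder_condition = resp,
    growth_multiplier = ifelse(is.na(resp), 1, growth_multiplier),
    active_ratio_logmean = log(active_ratio),
    inactive_ratio_logmean = log(inactive_ratio),
    ratio_logsd = ratio_logsd,
    persistent = pers,
    stringsAsFactors = FALSE
  )
}

validate_profiles <- function(profiles) {
  need <- c("taxon_id", "base_log_abundance", "dormant_fraction_baseline",
            "responder_condition", "growth_multiplier",
            "active_ratio_logmean", "inactive_ratio_logmean",
            "ratio_logsd", "persistent")
  missing <- setdiff(need, names(profiles))
  if (length(missing))
    stop_phantax(paste("profiles missing columns:",
                       paste(missing, collapse = ", ")), "configuration_error")
  if (any(exp(profiles$active_ratio_logmean) < 1) ||
      any(exp(profiles$inactive_ratio_logmean) >= 1))
    stop_phantax("active central ratio must be >= 1 and inactive < 1",
                 "configuration_error")
  if (any(profiles$growth_multiplier < 1))
    stop_phantax("growth_multiplier must be >= 1", "configuration_error")
  invisible(profiles)
}

# dormancy probability at pre-treatment baselines; field/pre_dry/post_dry
# carry elevated dormancy relative to the water-acclimated state
baseline_dormant_prob <- function(p, timepoint) {
  if (timepoint == "water_acclimated") p else pmin(1, p + 0.25)
}

#' Simulate latent abundances, activity states and ratios
#'
#' Draws the ground truth behind a paired DNA/cDNA experiment: for every
#' (taxon, biological sample) a latent DNA abundance, a Boolean activity
#' state, and a latent rRNA:rRNA-gene ratio. Responder taxa are inactive at
#' all pre-treatment baselines, reactivate at day1 only under their
#' responder condition (DNA abundance multiplied by `growth_multiplier`
#' while active), persist through day7/day14 if `persistent`, and revert
#' otherwise. Deterministic under `seed`.
#'
#' @param profiles taxon profile table, see [taxon_profiles()].
#' @param meta library metadata from [enumerate_design()] (only one row per
#'   pair is used; the DNA/cDNA pair shares its ground truth).
#' @param seed RNG seed.
#' @return data.frame of class `ground_truth`: one row per taxon x pair
#'   with `dna_abundance`, `active`, `ratio`.
#' @export
simulate_latent <- function(profiles, meta, seed = 1L) {
  validate_profiles(profiles)
  validate_metadata(meta)
  bio <- unique(meta[meta$nucleic_acid == "DNA",
                     c("pair_id", "soil", "treatment", "timepoint",
                       "mesocosm_id", "tech_rep")])
  if (!nrow(bio)) stop_phantax("no DNA libraries in metadata", "configuration_error")
  conds <- unique(bio$treatment)
  bad <- setdiff(stats::na.omit(unique(profiles$responder_condition)), conds)
  if (length(bad))
    stop_phantax(paste("responder_condition not in design conditions:",
                       paste(bad, collapse = ", ")), "configuration_error")
  set.seed(seed)

  n_taxa <- nrow(profiles)
  # activity states shared within taxon x mesocosm x timepoint
  unit_key <- paste(bio$mesocosm_id, bio$timepoint, sep = "|")
  units <- unique(data.frame(key = unit_key, treatment = bio$treatment,
                             timepoint = bio$timepoint, stringsAsFactors = FALSE))
  state_mat <- matrix(NA, n_taxa, nrow(units),
                      dimnames = list(profiles$taxon_id, units$key))
  for (u in seq_len(nrow(units))) {
    tp <- units$timepoint[u]
    trt <- units$treatment[u]
    is_resp <- !is.na(profiles$responder_condition)
    if (tp %in% BASELINE_TIMEPOINTS) {
      p_dorm <- baseline_dormant_prob(profiles$dormant_fraction_baseline, tp)
      st <- stats::runif(n_taxa) >= p_dorm
      st[is_resp] <- FALSE           # responders start dormant
    } else {
      st <- stats::runif(n_taxa) >= profiles$dormant_fraction_baseline
      in_own <- is_resp & profiles$responder_condition == trt
      st[is_resp] <- FALSE
      if (tp == "day1") {
        st[in_own] <- TRUE
      } else {
        st[in_own] <- profiles$persistent[in_own]
      }
    }
    state_mat[, u] <- st
  }

  # expand to pairs; draw per-pair ratios from the state lognormal
  pair_unit <- match(unit_key, units$key)
  out <- vector("list", nrow(bio))
  for (j in seq_len(nrow(bio))) {
    st <- state_mat[, pair_unit[j]]
    mult <- ifelse(st & !is.na(profiles$responder_condition),
                   profiles$growth_multiplier, 1)
    abund <- exp(profiles$base_log_abundance) * mult
    mu <- ifelse(st, profiles$active_ratio_logmean,
                 profiles$inactive_ratio_logmean)
    ratio <- stats::rlnorm(n_taxa, mu, profiles$ratio_logsd)
    out[[j]] <- data.frame(taxon_id = profiles$taxon_id,
                           pair_id = bio$pair_id[j],
                           dna_abundance = abund, active = st,
                           ratio = ratio, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, out)
  class(truth) <- c("ground_truth", "data.frame")
  truth
}

#' Sample sequencing reads from a ground truth
#'
#' Per library, counts are multinomial with probabilities proportional to
#' the latent DNA abundance (DNA library) or DNA abundance x latent ratio
#' (cDNA library). Library sizes are lognormal around `depth_mean` with
#' coefficient of variation `depth_cv`. Deterministic under `seed`.
#'
#' @param truth ground truth from [simulate_latent()].
#' @param meta library metadata.
#' @param depth_mean expected library size (reads).
#' @param depth_cv coefficient of variation of library sizes.
#' @param seed RNG seed.
#' @return list with integer count matrices `dna` and `cdna` (taxa x
#'   libraries, colnames are library sample IDs).
#' @export
sample_reads <- function(truth, meta, depth_mean = 12000, depth_cv = 0.2,
                         seed = 1L) {
  if (depth_mean < 1)
    stop_phantax("depth_mean must be >= 1", "configuration_error")
  validate_metadata(meta)
  taxa <- unique(truth$taxon_id)
  pairs <- unique(truth$pair_id)
  truth <- truth[order(match(truth$pair_id, pairs),
                       match(truth$taxon_id, taxa)), ]
  dna_ab <- matrix(truth$dna_abundance, length(taxa), length(pairs),
                   dimnames = list(taxa, pairs))
  rat <- matrix(truth$ratio, length(taxa), length(pairs),
                dimnames = list(taxa, pairs))
  if (any(colSums(dna_ab) <= 0))
    stop_phantax("a sample has an all-zero latent abundance vector",
                 "degenerate_sample")
  set.seed(seed)
  sdlog <- sqrt(log(1 + depth_cv^2))
  meanlog <- log(depth_mean) - sdlog^2 / 2
  draw <- function(prob_mat, ids) {
    depths <- pmax(1L, as.integer(round(stats::rlnorm(length(pairs),
                                                      meanlog, sdlog))))
    counts <- vapply(seq_along(pairs), function(j)
      stats::rmultinom(1L, depths[j], prob_mat[, j])[, 1L],
      integer(length(taxa)))
    if (!is.matrix(counts)) counts <- matrix(counts, nrow = length(taxa))
    dimnames(counts) <- list(taxa, ids)
    counts
  }
  id_of <- function(na) {
    m <- meta[meta$nucleic_acid == na, ]
    m$sample_id[match(pairs, m$pair_id)]
  }
  dna <- draw(dna_ab, id_of("DNA"))
  cdna <- draw(dna_ab * rat, id_of("cDNA"))
  list(dna = dna, cdna = cdna)
}

#' Simulate a full paired-library mesocosm experiment
#'
#' Convenience wrapper chaining [enumerate_design()], [simulate_latent()]
#' and [sample_reads()].
#'
#' @param spec a [design_spec()].
#' @param profiles taxon profile table; defaults to [taxon_profiles()]
#'   seeded from `spec$seed`.
#' @param depth_cv library-size coefficient of variation.
#' @return list with `dna`, `cdna` (count matrices), `meta`, `truth`,
#'   `profiles`.
#' @export
simulate_mesocosm <- function(spec = design_spec(), profiles = NULL,
                              depth_cv = 0.2) {
  meta <- enumerate_design(spec)
  if (is.null(profiles))
    profiles <- taxon_profiles(responder_conditions =
                                 intersect(c("ABA", "SA"), spec$conditions),
                               seed = spec$seed)
  truth <- simulate_latent(profiles, meta, seed = spec$seed + 1L)
  reads <- sample_reads(truth, meta, depth_mean = spec$depth_mean,
                        depth_cv = depth_cv, seed = spec$seed + 2L)
  list(dna = reads$dna, cdna = reads$cdna, meta = meta, truth = truth,
       profiles = profiles)
}
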