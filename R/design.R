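# BACI mesocosm design: enumeration of the sampling layout and the
# hormone carbon-dose calculator.

BASELINE_TIMEPOINTS <- c("field", "pre_dry", "post_dry", "water_acclimated")

#' Specify a BACI mesocosm design
#'
#' Describes the before-after-control-impact layout: soils, treatment
#' conditions (water and methanol-carrier controls plus hormone additions),
#' an ordered timepoint series, and replication. Baseline timepoints
#' (`field`, `pre_dry`, `post_dry`, `water_acclimated`) are sampled per
#' soil before any treatment; the remaining timepoints are sampled per
#' mesocosm after treatment.
#'
#' @param soils character vector of soil labels.
#' @param conditions character vector of condition labels; defaults to the
#'   water control, methanol carrier control, and the two phytohormones
#'   (abscisic acid, salicylic acid).
#' @param timepoints ordered unique timepoint labels.
#' @param mesocosm_reps mesocosm replicates per soil x condition.
#' @param tech_reps technical replicates per mesocosm x timepoint.
#' @param depth_mean expected library size in reads.
#' @param seed RNG seed carried along for the simulation stages.
#' @return object of class `design_spec`.
#' @export
design_spec <- function(soils = c("bean", "switchgrass"),
                        conditions = c("water", "methanol", "ABA", "SA"),
                        timepoints = c("water_acclimated", "day1", "day7", "day14"),
                        mesocosm_reps = 4L,
                        tech_reps = 3L,
                        depth_mean = 12000,
                        seed = 1L) {
  if (mesocosm_reps < 1 || tech_reps < 1 || depth_mean < 1)
    stop_phantax("mesocosm_reps, tech_reps and depth_mean must all be >= 1",
                 "invalid_design")
  if (anyDuplicated(timepoints))
    stop_phantax("timepoints must be unique", "invalid_design")
  if (anyDuplicated(soils) || anyDuplicated(conditions))
    stop_phantax("soils and conditions must be unique", "invalid_design")
  structure(list(soils = soils, conditions = conditions,
                 timepoints = timepoints,
                 mesocosm_reps = as.integer(mesocosm_reps),
                 tech_reps = as.integer(tech_reps),
                 depth_mean = depth_mean, seed = as.integer(seed)),
            class = "design_spec")
}

#' Enumerate all libraries of a BACI design
#'
#' Expands a [design_spec()] into one metadata row per sequencing library.
#' Each biological sample (a `pair_id`) yields two rows, a DNA and a cDNA
#' library. Treatment timepoints produce `mesocosm_reps * tech_reps`
#' biological samples per soil x condition x timepoint; baseline timepoints
#' produce `mesocosm_reps * tech_reps` per soil, with treatment `"none"`
#' and dedicated baseline mesocosm IDs (the paper-design arithmetic: 4
#' conditions x 4 replicates = 16 treatment mesocosms per soil, and 12
#' water-acclimated samples per soil).
#'
#' @param spec a [design_spec()].
#' @return data.frame of library metadata (see [read_sample_metadata()] for
#'   columns).
#' @export
enumerate_design <- function(spec) {
  if (!inherits(spec, "design_spec")) spec <- do.call(design_spec, spec)
  tp_base <- intersect(spec$timepoints, BASELINE_TIMEPOINTS)
  tp_treat <- setdiff(spec$timepoints, BASELINE_TIMEPOINTS)

  rows <- list()
  for (soil in spec$soils) {
    for (tp in tp_base) {
      g <- expand.grid(mes = seq_len(spec$mesocosm_reps),
                       tech = seq_len(spec$tech_reps))
      rows[[length(rows) + 1L]] <- data.frame(
        soil = soil, treatment = "none", timepoint = tp,
        mesocosm_id = sprintf("%s.base%d", soil, g$mes),
        tech_rep = g$tech, stringsAsFactors = FALSE)
    }
    for (cond in spec$conditions) {
      for (tp in tp_treat) {
        g <- expand.grid(mes = seq_len(spec$mesocosm_reps),
                         tech = seq_len(spec$tech_reps))
        rows[[length(rows) + 1L]] <- data.frame(
          soil = soil, treatment = cond, timepoint = tp,
          mesocosm_id = sprintf("%s.%s.m%d", soil, cond, g$mes),
          tech_rep = g$tech, stringsAsFactors = FALSE)
      }
    }
  }
  bio <- do.call(rbind, rows)
  bio$pair_id <- sprintf("%s.%s.%s.%s.t%d", bio$soil, bio$treatment,
                         bio$timepoint, sub("^.*\\.", "", bio$mesocosm_id),
                         bio$tech_rep)
  # expand each biological sample into a DNA and a cDNA library
  meta <- rbind(
    data.frame(bio, nucleic_acid = "DNA", stringsAsFactors = FALSE),
    data.frame(bio, nucleic_acid = "cDNA", stringsAsFactors = FALSE))
  meta$sample_id <- paste0(meta$pair_id, ".", meta$nucleic_acid)
  meta$is_negative_control <- FALSE
  meta <- meta[order(meta$pair_id, meta$nucleic_acid), required_meta_cols]
  rownames(meta) <- NULL
  validate_metadata(meta)
  meta
}

#' Summarise design arithmetic
#'
#' Counts of treatment mesocosms, biological samples and libraries for a
#' metadata table, overall and per soil.
#'
#' @param meta library metadata from [enumerate_design()].
#' @return list with `n_mesocosms` (treatment mesocosms), `n_mesocosms_per_soil`,
#'   `n_biological`, `n_libraries`, and `n_per_soil_treatment_timepoint`.
#' @export
design_counts <- function(meta) {
  trt <- meta[meta$treatment != "none", ]
  per_stp <- if (nrow(trt)) table(trt$soil, trt$treatment, trt$timepoint) / 2 else NULL
  list(
    n_mesocosms = length(unique(trt$mesocosm_id)),
    n_mesocosms_per_soil = if (nrow(trt))
      vapply(split(trt$mesocosm_id, trt$soil),
             function(x) length(unique(x)), 1L) else integer(),
    n_biological = length(unique(meta$pair_id)),
    n_libraries = nrow(meta),
    n_per_soil_treatment_timepoint = per_stp
  )
}

#' Carbon dose of a dissolved amendment
#'
#' Micrograms of carbon added per gram of dry soil when a `volume` mL
#' aliquot of a `molarity` mol/L solution of a molecule containing
#' `carbon_atoms_per_molecule` carbon atoms is added to `soil_mass` g of
#' dry soil. The molar mass of carbon is fixed at 12.011 g/mol.
#'
#' @param molarity solution concentration, mol/L.
#' @param volume volume added, mL.
#' @param carbon_atoms_per_molecule carbon atoms per molecule (7 for
#'   salicylic acid C7H6O3, 15 for abscisic acid C15H20O4).
#' @param soil_mass dry soil mass, g; must be positive.
#' @return dose in micrograms carbon per gram dry soil.
#' @examples
#' carbon_dose(0.3, 1, 7, 100)   # salicylic acid recipe, ~252 ug C/g
#' carbon_dose(0.3, 1, 15, 100)  # abscisic acid recipe, ~541 ug C/g
#' @export
carbon_dose <- function(molarity, volume, carbon_atoms_per_molecule, soil_mass) {
  if (any(c(molarity, volume, carbon_atoms_per_molecule) < 0))
    stop_phantax("molarity, volume and carbon count must be non-negative",
                 "invalid_input")
  if (any(soil_mass <= 0))
    stop_phantax("soil_mass must be positive", "invalid_input")
  molarity * (volume / 1000) * carbon_atoms_per_molecule * 12.011 * 1e6 / soil_mass
}
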