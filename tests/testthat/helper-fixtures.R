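# Shared fixture builders: all fixtures are generated in code.

make_counts <- function(vals, taxa = NULL, samples = NULL) {
  m <- if (is.matrix(vals)) vals else
    matrix(vals, nrow = length(taxa) %||% nrow(vals))
  if (is.null(taxa)) taxa <- sprintf("t%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(taxa, samples)
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_counts <- function(n_taxa, n_samples, lambda = 10, seed = 1) {
  set.seed(seed)
  make_counts(matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples))
}

# minimal paired metadata for n biological samples of one condition
simple_meta <- function(pair_ids, soil = "bean", treatment = "water",
                        timepoint = "day1") {
  n <- length(pair_ids)
  data.frame(
    sample_id = c(paste0(pair_ids, ".DNA"), paste0(pair_ids, ".cDNA")),
    nucleic_acid = rep(c("DNA", "cDNA"), each = n),
    soil = soil, treatment = treatment, timepoint = timepoint,
    mesocosm_id = rep(paste0("m", seq_len(n)), 2), tech_rep = 1L,
    is_negative_control = FALSE, pair_id = rep(pair_ids, 2),
    stringsAsFactors = FALSE)
}

# small simulated experiment reused across test files (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- design_spec(depth_mean = 5000, mesocosm_reps = 2L,
                          tech_reps = 2L, seed = 7L)
      cache <<- simulate_mesocosm(spec)
    }
    cache
  }
})

# the standard-design fixture (full replication, deep sequencing) with the
# activity classifier already run on rarefied paired libraries; cached
# because several recovery checks share it
standard_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_mesocosm(design_spec(depth_mean = 50000, seed = 7L))
      dr <- rarefy(sim$dna, 30000, seed = 11)
      cr <- rarefy(sim$cdna, 30000, seed = 12)
      paired <- pair_libraries(dr, cr, sim$meta)
      calls <- classify_activity(phantom_adjust(paired$dna, paired$cdna),
                                 paired$cdna)
      sim$paired <- paired
      sim$calls <- calls
      cache <<- sim
    }
    cache
  }
})
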