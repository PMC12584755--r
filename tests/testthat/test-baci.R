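# Hand-built calls object: one soil, baseline (12 replicates) plus day1/7/14
# of one treatment (12 replicates each), with taxa of known dynamics.
make_baci_fixture <- function(active_counts) {
  # active_counts: named list taxon -> c(baseline, day1, day7, day14)
  # number of ACTIVE replicates out of 12 at each condition
  tps <- c("water_acclimated", "day1", "day7", "day14")
  trts <- c("none", "ABA", "ABA", "ABA")
  pair_ids <- unlist(lapply(seq_along(tps), function(i)
    sprintf("%s.%s.r%d", trts[i], tps[i], 1:12)))
  meta <- data.frame(
    sample_id = c(paste0(pair_ids, ".DNA"), paste0(pair_ids, ".cDNA")),
    nucleic_acid = rep(c("DNA", "cDNA"), each = length(pair_ids)),
    soil = "bean",
    treatment = rep(rep(trts, each = 12), 2),
    timepoint = rep(rep(tps, each = 12), 2),
    mesocosm_id = rep(rep(sprintf("m%d", rep(1:4, each = 3)), 4), 2),
    tech_rep = rep(rep(1:3, 16), 2),
    is_negative_control = FALSE,
    pair_id = rep(pair_ids, 2), stringsAsFactors = FALSE)
  taxa <- names(active_counts)
  state <- matrix("I", length(taxa), length(pair_ids),
                  dimnames = list(taxa, pair_ids))
  dna <- matrix(5L, length(taxa), length(pair_ids),
                dimnames = list(taxa, pair_ids))
  rna <- matrix(1L, length(taxa), length(pair_ids),
                dimnames = list(taxa, pair_ids))
  for (t in taxa) {
    for (i in seq_along(tps)) {
      cols <- sprintf("%s.%s.r%d", trts[i], tps[i], seq_len(active_counts[[t]][i]))
      state[t, cols] <- "A"
      rna[t, cols] <- 10L
    }
  }
  calls <- structure(list(ratio = rna / dna, state = state, dna = dna,
                          rna = rna, threshold = 1),
                     class = "activity_calls")
  list(calls = calls, meta = meta, dna = dna)
}

test_that("consistency scores are replicate fractions, invariant to order", {
  fx <- make_baci_fixture(list(a = c(0, 12, 6, 0)))
  expect_equal(consistency_score(fx$calls, fx$meta, "a", "bean", "ABA", "day1"), 1.0)
  expect_equal(consistency_score(fx$calls, fx$meta, "a", "bean", "ABA", "day7"), 0.5)
  expect_equal(consistency_score(fx$calls, fx$meta, "a", "bean", "ABA", "day14"), 0.0)
  # permuting the pair columns leaves the score unchanged
  perm <- sample(ncol(fx$calls$state))
  shuffled <- fx$calls
  shuffled$state <- shuffled$state[, perm, drop = FALSE]
  shuffled$ratio <- shuffled$ratio[, perm, drop = FALSE]
  expect_equal(consistency_score(shuffled, fx$meta, "a", "bean", "ABA", "day7"), 0.5)
  expect_error(consistency_score(fx$calls, fx$meta, "a", "bean", "SA", "day1"),
               class = "missing_condition")
})

test_that("reactivation requires a fully quiet baseline and a consistent day 1", {
  fx <- make_baci_fixture(list(
    react = c(0, 10, 0, 0),     # quiet baseline, 10/12 at day1
    basal = c(6, 12, 12, 12),   # active at baseline: never 'reactivated'
    weak  = c(0, 5, 0, 0)))     # day1 consistency 5/12 < 0.5
  expect_true(classify_reactivation(fx$calls, fx$meta, "react", "bean", "ABA"))
  expect_false(classify_reactivation(fx$calls, fx$meta, "basal", "bean", "ABA"))
  expect_false(classify_reactivation(fx$calls, fx$meta, "weak", "bean", "ABA"))
  # monotone in c_min: raising the cut never adds positives
  expect_true(classify_reactivation(fx$calls, fx$meta, "weak", "bean", "ABA",
                                    c_min = 0.25))
  expect_error(classify_reactivation(fx$calls, fx$meta, "react", "bean", "ABA",
                                     baseline_timepoint = "pre_dry"),
               class = "missing_baseline")
})

test_that("persistence needs sustained consistency through day 14", {
  fx <- make_baci_fixture(list(
    persist = c(0, 12, 11, 10),  # 1.0 / ~0.9 / ~0.8
    fade    = c(0, 12, 0, 0)))
  expect_true(classify_persistence(fx$calls, fx$meta, "persist", "bean", "ABA"))
  expect_false(classify_persistence(fx$calls, fx$meta, "fade", "bean", "ABA"))
  expect_error(classify_persistence(fx$calls, fx$meta, "persist", "bean", "SA"),
               class = "partial_series")
})

test_that("treatment specificity excludes taxa responsive to the controls", {
  hormone <- list(log2fc = 5.1, padj = 0.003)
  meth_null <- list(log2fc = 0.2, padj = 0.8)
  water_null <- list(log2fc = 0.1, padj = 0.9)
  expect_true(classify_treatment_specificity(hormone, meth_null, water_null))
  # also significant in the carrier control: not specific
  meth_sig <- list(log2fc = 3.0, padj = 0.01)
  expect_false(classify_treatment_specificity(hormone, meth_sig, water_null))
  # significant p but weak fold change fails the enrichment definition
  expect_false(classify_treatment_specificity(list(log2fc = 0.5, padj = 0.001),
                                              meth_null, water_null))
  expect_error(classify_treatment_specificity(list(log2fc = NA, padj = NA),
                                              meth_null, water_null),
               class = "incomplete_evidence")
})

test_that("top-active selection ranks by summed counts with deterministic ties", {
  fx <- make_baci_fixture(list(a = c(0, 12, 12, 12), b = c(0, 12, 12, 12),
                               c = c(0, 12, 12, 12)))
  act <- fx$dna
  act["a", ] <- 7L  # higher total than b, c (ties broken by ID)
  top2 <- select_top_active(act, fx$meta, "bean", "ABA", n = 2)
  expect_identical(top2, c("a", "b"))
  expect_identical(top2, select_top_active(act, fx$meta, "bean", "ABA", n = 2))
  expect_message(all3 <- select_top_active(act, fx$meta, "bean", "ABA", n = 50),
                 "returning all")
  expect_identical(all3, c("a", "b", "c"))
})

test_that("the transition report aggregates flags across strata", {
  fx <- make_baci_fixture(list(
    react_persist = c(0, 12, 12, 12),
    react_fade = c(0, 12, 0, 0),
    basal = c(12, 12, 12, 12)))
  tr <- baci_transitions(fx$calls, fx$meta, fx$dna)
  rp <- tr[tr$taxon_id == "react_persist", ]
  expect_true(rp$reactivated && rp$persistent)
  rf <- tr[tr$taxon_id == "react_fade", ]
  expect_true(rf$reactivated && !rf$persistent)
  ba <- tr[tr$taxon_id == "basal", ]
  expect_true(!ba$reactivated && ba$persistent)
  expect_true(all(tr$baseline_consistency >= 0 & tr$baseline_consistency <= 1))

  long <- activity_long_table(fx$calls, fx$meta, fx$dna)
  expect_setequal(unique(long$timepoint), c("day1", "day7", "day14"))
  expect_true(all(long$state %in% c("A", "I", "+")))
  expect_true(all(long$relabund >= 0 & long$relabund <= 1))
})

test_that("planted responders are recovered from a simulated experiment", {
  sim <- standard_sim()
  calls <- sim$calls
  tr <- baci_transitions(calls, sim$meta,
                         suppressWarnings(active_community(sim$paired$dna, calls)))
  resp <- sim$profiles[!is.na(sim$profiles$responder_condition), ]
  hit <- merge(tr, resp, by = "taxon_id")
  own <- hit[hit$treatment == hit$responder_condition, ]
  expect_gte(mean(own$reactivated), 0.9)
  non <- tr[!tr$taxon_id %in% resp$taxon_id, ]
  expect_lte(mean(non$reactivated), 0.05)
})
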