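# Activity designation: phantom-taxon adjustment, rRNA:rRNA-gene ratios,
# threshold classification, and the active-community DNA table.

#' Phantom-taxon adjustment
#'
#' A "phantom taxon" is observed in the cDNA (RNA) library but has zero
#' reads in the paired DNA library. Every cell with DNA = 0 and RNA > 0 is
#' set to DNA = 1 so its ratio is defined; all other cells are unchanged.
#'
#' @param dna,rna taxon-aligned count matrices (taxa x pairs), e.g. from
#'   [pair_libraries()].
#' @return adjusted DNA matrix with attribute `n_adjusted`, the number of
#'   phantom cells.
#' @export
phantom_adjust <- function(dna, rna) {
  validate_count_table(dna, "dna")
  validate_count_table(rna, "rna")
  check_aligned(dna, rna, "dna and rna tables")
  phantom <- dna == 0L & rna > 0L
  dna[phantom] <- 1L
  attr(dna, "n_adjusted") <- sum(phantom)
  dna
}

#' rRNA:rRNA-gene ratio matrix
#'
#' Element-wise RNA/DNA on phantom-adjusted counts. After the phantom
#' adjustment, DNA = 0 implies RNA = 0, where the ratio is undefined and
#' returned as `NA`.
#'
#' @param adjusted_dna phantom-adjusted DNA matrix from [phantom_adjust()].
#' @param rna aligned RNA (cDNA) count matrix.
#' @return real matrix of ratios (`NA` where undetected).
#' @export
compute_ratios <- function(adjusted_dna, rna) {
  validate_count_table(adjusted_dna, "adjusted_dna")
  validate_count_table(rna, "rna")
  check_aligned(adjusted_dna, rna, "adjusted_dna and rna")
  if (any(adjusted_dna == 0L & rna > 0L))
    stop_phantax("rna > 0 where dna = 0: apply phantom_adjust() first",
                 "validation_error")
  ratio <- rna / adjusted_dna
  ratio[adjusted_dna == 0L] <- NA_real_
  ratio
}

#' Classify per-sample activity states
#'
#' Applies the rRNA:rRNA-gene ratio threshold: a taxon is ACTIVE in a
#' sample pair when its RNA count is positive and its ratio is at least
#' `threshold` (inclusive; default 1), INACTIVE when detected but not
#' active, and NOT_DETECTED when absent from both libraries.
#'
#' @param adjusted_dna,rna aligned matrices (post [phantom_adjust()]).
#' @param threshold activity ratio threshold, > 0.
#' @return object of class `activity_calls`: list with matrices `ratio`,
#'   `state` (`"A"`, `"I"`, `"+"` for not detected), `dna`, `rna`, and the
#'   `threshold`.
#' @export
classify_activity <- function(adjusted_dna, rna, threshold = 1.0) {
  if (threshold <= 0)
    stop_phantax("threshold must be positive", "configuration_error")
  ratio <- compute_ratios(adjusted_dna, rna)
  state <- matrix("I", nrow(rna), ncol(rna), dimnames = dimnames(rna))
  state[rna > 0L & !is.na(ratio) & ratio >= threshold] <- "A"
  state[adjusted_dna == 0L & rna == 0L] <- "+"
  structure(list(ratio = ratio, state = state, dna = adjusted_dna,
                 rna = rna, threshold = threshold),
            class = "activity_calls")
}

#' @export
print.activity_calls <- function(x, ...) {
  tab <- table(factor(x$state, c("A", "I", "+")))
  cat(sprintf("Activity calls: %d taxa x %d sample pairs (threshold %.3g)\n",
              nrow(x$state), ncol(x$state), x$threshold))
  cat(sprintf("  ACTIVE %d | INACTIVE %d | NOT_DETECTED %d\n",
              tab[["A"]], tab[["I"]], tab[["+"]]))
  invisible(x)
}

#' @export
summary.activity_calls <- function(object, ...) {
  per_pair <- colMeans(object$state == "A")
  out <- list(threshold = object$threshold,
              n_taxa = nrow(object$state),
              n_pairs = ncol(object$state),
              state_counts = table(factor(object$state, c("A", "I", "+"))),
              active_fraction_per_pair = per_pair)
  class(out) <- "summary.activity_calls"
  out
}

#' @export
print.summary.activity_calls <- function(x, ...) {
  cat(sprintf("Activity calls at threshold %.3g: %d taxa, %d pairs\n",
              x$threshold, x$n_taxa, x$n_pairs))
  print(x$state_counts)
  cat("Active fraction per pair:\n")
  print(summary(x$active_fraction_per_pair))
  invisible(x)
}

#' Build the active-community DNA table
#'
#' DNA counts of likely-active taxa (DNA rather than RNA counts are used to
#' limit relative-transcription biases across taxa). By default entries are
#' zeroed per sample wherever the taxon is not ACTIVE there, and taxa
#' active in no sample are dropped; with `per_sample = FALSE` a taxon
#' active in any sample keeps its whole DNA row (global filter).
#'
#' @param dna DNA count matrix aligned with `calls` (the unadjusted counts
#'   are the usual input).
#' @param calls an [classify_activity()] result on the same pairing.
#' @param per_sample zero per-sample inactive entries (default) or filter
#'   whole taxa only.
#' @return filtered DNA count matrix; warns when empty.
#' @export
active_community <- function(dna, calls, per_sample = TRUE) {
  validate_count_table(dna, "dna")
  if (!inherits(calls, "activity_calls"))
    stop_phantax("calls must be an activity_calls object", "validation_error")
  check_aligned(dna, calls$state, "dna and activity calls")
  active <- calls$state == "A"
  out <- dna
  if (per_sample) out[!active] <- 0L
  keep <- rowSums(active) > 0
  if (!any(keep)) warning("no taxa are active in any sample")
  out[keep, , drop = FALSE]
}
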