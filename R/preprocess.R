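# Preprocessing: pairing DNA/cDNA libraries, rarefaction, contaminant and
# organelle filtering, max standardization.

#' Pair DNA and cDNA libraries via metadata
#'
#' Matches DNA and cDNA libraries that share a `pair_id`. Only complete
#' pairs are returned; the taxon universes of the two tables are unioned,
#' with taxa missing from one table filled with zero counts, so the paired
#' matrices are taxon-aligned (a prerequisite for the phantom-taxon rule).
#'
#' @param dna,cdna count matrices (taxa x samples).
#' @param meta library metadata with `sample_id`, `nucleic_acid`, `pair_id`.
#' @return list with taxon-aligned matrices `dna` and `cdna` whose columns
#'   are pair IDs, a `pairs` data.frame mapping pair to library IDs, and
#'   `unpaired`, the library IDs excluded for lack of a partner.
#' @export
pair_libraries <- function(dna, cdna, meta) {
  validate_count_table(dna, "dna")
  validate_count_table(cdna, "cdna")
  validate_metadata(meta)
  md <- meta[meta$nucleic_acid == "DNA" & meta$sample_id %in% colnames(dna), ]
  mc <- meta[meta$nucleic_acid == "cDNA" & meta$sample_id %in% colnames(cdna), ]
  common <- intersect(md$pair_id, mc$pair_id)
  if (!length(common))
    stop_phantax("no complete DNA/cDNA pairs found", "empty_pairing")
  pairs <- data.frame(
    pair_id = common,
    dna_sample = md$sample_id[match(common, md$pair_id)],
    cdna_sample = mc$sample_id[match(common, mc$pair_id)],
    stringsAsFactors = FALSE)
  unpaired <- setdiff(c(md$sample_id, mc$sample_id),
                      c(pairs$dna_sample, pairs$cdna_sample))
  taxa <- union(rownames(dna), rownames(cdna))
  expand <- function(x, cols) {
    out <- matrix(0L, length(taxa), length(cols),
                  dimnames = list(taxa, cols))
    out[rownames(x), ] <- x[, cols, drop = FALSE]
    out
  }
  d <- expand(dna, pairs$dna_sample)
  r <- expand(cdna, pairs$cdna_sample)
  colnames(d) <- colnames(r) <- pairs$pair_id
  list(dna = d, cdna = r, pairs = pairs, unpaired = unpaired)
}

#' Rarefy a count table to fixed depth
#'
#' Subsamples each library without replacement (multivariate
#' hypergeometric) to exactly `depth` reads. Libraries whose total is below
#' `depth` are dropped and reported in the `dropped` attribute; a library
#' whose total equals `depth` is returned unchanged. Deterministic under
#' `seed`.
#'
#' @param table count matrix (taxa x samples).
#' @param depth target reads per library; the analysis default is 12000.
#' @param seed RNG seed.
#' @return rarefied integer matrix with attribute `dropped` naming removed
#'   libraries.
#' @export
rarefy <- function(table, depth = 12000, seed = 1L) {
  validate_count_table(table)
  if (depth < 1) stop_phantax("depth must be >= 1", "configuration_error")
  totals <- colSums(table)
  keep <- totals >= depth
  if (!any(keep))
    stop_phantax("all samples fall below the rarefaction depth", "empty_table")
  dropped <- colnames(table)[!keep]
  out <- table[, keep, drop = FALSE]
  set.seed(seed)
  for (j in seq_len(ncol(out))) {
    tot <- totals[keep][j]
    if (tot == depth) next
    reads <- sample.int(tot, depth)       # positions among the tot reads
    cuts <- cumsum(out[, j])
    out[, j] <- tabulate(findInterval(reads - 1L, c(0L, cuts),
                                      left.open = FALSE), nrow(out))
  }
  storage.mode(out) <- "integer"
  attr(out, "dropped") <- dropped
  out
}

#' Flag likely contaminant taxa using negative controls
#'
#' Prevalence screen: for each taxon, a one-sided hypergeometric
#' (Fisher-exact) test of whether presence is over-represented in negative
#' controls relative to true samples. A taxon is flagged when its
#' prevalence fraction is strictly greater in the negatives and the
#' one-sided p-value is at most `alpha`.
#'
#' @param table count matrix including negative-control libraries.
#' @param meta metadata with `is_negative_control`.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame per tested taxon with prevalences and p-value, and a
#'   logical `flagged` column; empty with a warning when no negative
#'   controls are present.
#' @export
flag_contaminants <- function(table, meta, alpha = 0.05) {
  validate_count_table(table)
  neg_ids <- meta$sample_id[meta$is_negative_control &
                              meta$sample_id %in% colnames(table)]
  true_ids <- setdiff(colnames(table), neg_ids)
  if (!length(neg_ids)) {
    warning("no negative controls present; contaminant screen skipped")
    return(data.frame(taxon_id = character(), prev_neg = numeric(),
                      prev_true = numeric(), p = numeric(),
                      flagged = logical()))
  }
  if (!length(true_ids))
    stop_phantax("no true samples present", "configuration_error")
  pres <- table > 0
  x_neg <- rowSums(pres[, neg_ids, drop = FALSE])
  x_true <- rowSums(pres[, true_ids, drop = FALSE])
  n_neg <- length(neg_ids); n_true <- length(true_ids)
  # one-sided Fisher: P(presences in negatives >= observed) under the
  # hypergeometric null; equals fisher.test(alternative = "greater")
  p <- stats::phyper(x_neg - 1, x_neg + x_true,
                     n_neg + n_true - x_neg - x_true, n_neg,
                     lower.tail = FALSE)
  prev_neg <- x_neg / n_neg
  prev_true <- x_true / n_true
  data.frame(taxon_id = rownames(table), prev_neg = prev_neg,
             prev_true = prev_true, p = p,
             flagged = prev_neg > prev_true & p <= alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove organelle and otherwise banned lineages
#'
#' Drops taxa whose taxonomy string contains a banned term
#' (case-insensitive, any rank). Taxa missing from the taxonomy table are
#' retained with a warning.
#'
#' @param table count matrix.
#' @param taxonomy data.frame with `taxon_id` plus rank columns.
#' @param banned_terms terms to remove; default mitochondria and
#'   chloroplast sequences.
#' @return filtered matrix with attribute `removed` naming removed taxa.
#' @export
filter_taxonomy <- function(table, taxonomy,
                            banned_terms = c("Mitochondria", "Chloroplast")) {
  validate_count_table(table)
  if (!length(banned_terms)) {
    attr(table, "removed") <- character()
    return(table)
  }
  idx <- match(rownames(table), taxonomy$taxon_id)
  if (anyNA(idx))
    warning(sprintf("%d taxa missing from the taxonomy table were retained",
                    sum(is.na(idx))))
  rank_cols <- setdiff(names(taxonomy), "taxon_id")
  strings <- do.call(paste, c(taxonomy[idx, rank_cols, drop = FALSE], sep = ";"))
  strings[is.na(idx)] <- ""
  hit <- Reduce(`|`, lapply(banned_terms, function(term)
    grepl(term, strings, ignore.case = TRUE)))
  out <- table[!hit, , drop = FALSE]
  attr(out, "removed") <- rownames(table)[hit]
  out
}

#' Max-standardize a table by taxon
#'
#' Divides each taxon row by its row maximum, so every non-zero row attains
#' a maximum of exactly 1; all-zero rows are left as zero. Used for
#' relative-abundance bubble displays of activity dynamics.
#'
#' @param table numeric matrix (taxa x samples).
#' @return real-valued matrix of the same shape.
#' @export
max_standardize <- function(table) {
  if (!is.matrix(table) || !is.numeric(table))
    stop_phantax("table must be a numeric matrix", "validation_error")
  rmax <- apply(table, 1, max)
  sweep(table, 1, ifelse(rmax > 0, rmax, 1), "/")
}
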