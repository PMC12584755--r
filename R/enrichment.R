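# Simplified negative-binomial Wald contrast for two-condition
# differential abundance: median-of-ratios normalization, method-of-moments
# dispersion, delta-method standard error on the log2 fold change, BH-FDR.
#
# This is deliberately a minimal, fully documented contrast — no dispersion
# trend shrinkage, no outlier filtering, no fold-change shrinkage.

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors: the median, over reference taxa with
#' positive counts in every sample, of the ratio of each taxon's count to
#' its geometric mean across samples. Falls back to library-size
#' normalization (scaled to geometric mean 1) with a warning when no
#' reference taxa exist.
#'
#' @param table count matrix (taxa x samples).
#' @return named positive numeric vector, one per sample.
#' @export
size_factors_median_ratio <- function(table) {
  validate_count_table(table)
  ref <- rowSums(table > 0) == ncol(table)
  if (!any(ref)) {
    warning("no taxon is present in all samples; using library-size factors")
    libs <- colSums(table)
    if (any(libs == 0))
      stop_phantax("a sample has zero total counts", "validation_error")
    return(libs / exp(mean(log(libs))))
  }
  x <- table[ref, , drop = FALSE]
  gm <- exp(rowMeans(log(x)))
  apply(x / gm, 2, stats::median)
}

#' Method-of-moments NB dispersion
#'
#' For one taxon's normalized counts, grouped by condition: per-group
#' `alpha_g = (s2_g - m_g) / m_g^2`, pooled by degrees of freedom and
#' floored at `alpha_min`. With a single group, supply one grouping level.
#'
#' @param x numeric vector of normalized counts.
#' @param groups grouping factor (>= 2 replicates per group).
#' @param alpha_min dispersion floor (default 1e-8).
#' @return scalar dispersion estimate, >= `alpha_min`.
#' @export
estimate_dispersion <- function(x, groups = rep(1L, length(x)),
                                alpha_min = 1e-8) {
  groups <- as.factor(groups)
  ns <- tabulate(groups)
  if (any(ns < 2))
    stop_phantax("each group needs >= 2 replicates", "configuration_error")
  m <- tapply(x, groups, mean)
  v <- tapply(x, groups, stats::var)
  ok <- m > 0
  if (!any(ok)) return(alpha_min)
  a <- (v[ok] - m[ok]) / m[ok]^2
  w <- as.numeric(table(groups)[ok]) - 1
  pooled <- sum(a * w) / sum(w)
  max(alpha_min, pooled)
}

#' Negative-binomial Wald contrast between two groups
#'
#' For each taxon: counts are normalized by `size_factors`; the log2 fold
#' change is `log2((mB + eps) / (mA + eps))` on group means of normalized
#' counts; its standard error comes from the delta method using the NB
#' variance `m + alpha m^2` of each group mean; the two-sided Wald p-value
#' uses the normal tail; BH adjustment is applied across tested taxa.
#' All-zero taxa are excluded from testing and reported with `NA` results.
#'
#' @param table count matrix containing both groups.
#' @param size_factors per-sample factors computed on the union (default:
#'   [size_factors_median_ratio()] of the two groups' columns).
#' @param groupA,groupB disjoint character vectors of sample IDs; the fold
#'   change is B relative to A (baseline A).
#' @param epsilon pseudo-count on normalized group means (default 0.5).
#' @param alpha_min dispersion floor.
#' @return data.frame of class `contrast_result` with `taxon_id`,
#'   `base_mean`, `log2fc`, `se`, `wald_p`, `padj`.
#' @export
nb_wald_contrast <- function(table, size_factors = NULL, groupA, groupB,
                             epsilon = 0.5, alpha_min = 1e-8) {
  validate_count_table(table)
  if (length(intersect(groupA, groupB)))
    stop_phantax("groupA and groupB overlap", "design_error")
  if (!length(groupA) || !length(groupB))
    stop_phantax("both groups must be non-empty", "design_error")
  miss <- setdiff(c(groupA, groupB), colnames(table))
  if (length(miss))
    stop_phantax(paste("samples not in table:", paste(miss, collapse = ", ")),
                 "design_error")
  cols <- c(groupA, groupB)
  sub <- table[, cols, drop = FALSE]
  if (is.null(size_factors))
    size_factors <- size_factors_median_ratio(sub)
  sf <- size_factors[cols]
  if (anyNA(sf) || any(sf <= 0))
    stop_phantax("size factors must be positive for every sample",
                 "validation_error")
  norm <- sweep(sub, 2, sf, "/")
  ja <- seq_along(groupA)
  jb <- length(groupA) + seq_along(groupB)
  nA <- length(ja); nB <- length(jb)
  mA <- rowMeans(norm[, ja, drop = FALSE])
  mB <- rowMeans(norm[, jb, drop = FALSE])
  vA <- apply(norm[, ja, drop = FALSE], 1, stats::var)
  vB <- apply(norm[, jb, drop = FALSE], 1, stats::var)
  tested <- mA + mB > 0
  alpha <- rep(alpha_min, nrow(sub))
  for (i in which(tested)) {
    parts <- c(if (mA[i] > 0 && nA > 1) (vA[i] - mA[i]) / mA[i]^2,
               if (mB[i] > 0 && nB > 1) (vB[i] - mB[i]) / mB[i]^2)
    wts <- c(if (mA[i] > 0 && nA > 1) nA - 1, if (mB[i] > 0 && nB > 1) nB - 1)
    if (length(parts)) alpha[i] <- max(alpha_min, sum(parts * wts) / sum(wts))
  }
  log2fc <- log2((mB + epsilon) / (mA + epsilon))
  varA <- (mA + alpha * mA^2) / nA
  varB <- (mB + alpha * mB^2) / nB
  ln2sq <- log(2)^2
  se <- sqrt(varA / ((mA + epsilon)^2 * ln2sq) +
               varB / ((mB + epsilon)^2 * ln2sq))
  se[tested & se == 0] <- NA  # degenerate: identical constant groups
  z <- log2fc / se
  wald_p <- 2 * stats::pnorm(-abs(z))
  wald_p[!tested] <- NA
  log2fc[!tested] <- NA
  padj <- rep(NA_real_, length(wald_p))
  padj[!is.na(wald_p)] <- bh_adjust(wald_p[!is.na(wald_p)])
  out <- data.frame(taxon_id = rownames(sub),
                    base_mean = (mA * nA + mB * nB) / (nA + nB),
                    log2fc = log2fc, se = se, wald_p = wald_p, padj = padj,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (monotone, order-preserving); validates the
#' inputs and delegates to the standard implementation.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, component-wise >= input and <= 1.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop_phantax("p-values must lie in [0, 1]", "validation_error")
  stats::p.adjust(pvals, method = "BH")
}

#' Enriched taxon set
#'
#' Taxa with `padj <= fdr` and `log2fc >= lfc_min` ("log twofold increase"
#' at `lfc_min = 1`).
#'
#' @param results a [nb_wald_contrast()] result.
#' @param fdr FDR threshold (default 0.05).
#' @param lfc_min minimum log2 fold change (default 1).
#' @return character vector of taxon IDs.
#' @export
enriched_set <- function(results, fdr = 0.05, lfc_min = 1.0) {
  keep <- !is.na(results$padj) & results$padj <= fdr &
    !is.na(results$log2fc) & results$log2fc >= lfc_min
  results$taxon_id[keep]
}
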