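# Diversity and multivariate community statistics: richness, inverse
# Simpson, Bray-Curtis, permutation PERMANOVA (optionally stratified),
# PCoA, partial constrained ordination, Kruskal-Wallis.

#' Richness and inverse Simpson diversity
#'
#' Richness counts taxa with positive counts. Inverse Simpson is
#' `1 / sum(p_i^2)` on relative abundances, accounting for both richness
#' and evenness; it equals S for a uniform S-taxon community.
#'
#' @param counts non-negative numeric vector of one sample's counts.
#' @return integer (richness) or real (inverse Simpson).
#' @export
richness <- function(counts) {
  if (any(counts < 0)) stop_phantax("counts must be non-negative",
                                    "validation_error")
  sum(counts > 0)
}

#' @rdname richness
#' @export
inverse_simpson <- function(counts) {
  if (any(counts < 0)) stop_phantax("counts must be non-negative",
                                    "validation_error")
  tot <- sum(counts)
  if (tot == 0)
    stop_phantax("inverse Simpson undefined for an all-zero sample",
                 "validation_error")
  p <- counts / tot
  1 / sum(p^2)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` between sample columns.
#' On equal-depth (rarefied) samples this equals the relative-abundance
#' formulation exactly.
#'
#' @param table numeric matrix (taxa x samples), >= 2 samples with
#'   positive totals.
#' @return a `dist` object over samples.
#' @export
bray_curtis <- function(table) {
  if (!is.matrix(table) || ncol(table) < 2)
    stop_phantax("need a matrix with >= 2 samples", "validation_error")
  if (any(table < 0)) stop_phantax("counts must be non-negative",
                                   "validation_error")
  tot <- colSums(table)
  n <- ncol(table)
  d <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      denom <- tot[i] + tot[j]
      if (denom == 0)
        stop_phantax(sprintf("distance undefined between all-zero samples %s and %s",
                             colnames(table)[i], colnames(table)[j]),
                     "undefined_distance")
      d[i, j] <- d[j, i] <- sum(abs(table[, i] - table[, j])) / denom
    }
  }
  stats::as.dist(d)
}

# sum over groups of within-group mean squared distances (the PERMANOVA
# within sum of squares), from the squared distance matrix
ss_within <- function(D2, groups) {
  s <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1)
      s <- s + sum(D2[idx, idx]) / (2 * length(idx))
  }
  s
}

all_label_permutations <- function(n) {
  if (n > 9) stop_phantax("exhaustive enumeration limited to n <= 9",
                          "configuration_error")
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  perms(seq_len(n))
}

#' Permutation PERMANOVA on a distance matrix
#'
#' Partitions the total sum of squared distances into between- and
#' within-group components: `SS_total = sum_{i<j} d_ij^2 / n`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`, and
#' `pseudo-F = (SS_between/df_between) / (SS_within/df_within)`. The
#' p-value comes from label permutations with the add-one rule,
#' `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)`; with
#' `n_perm = "exhaustive"` all `n!` label permutations are enumerated and
#' `p = #[F >= F_obs] / n!`. When `strata` is given, labels are permuted
#' only within strata.
#'
#' @param d `dist` object or symmetric distance matrix.
#' @param groups grouping factor (>= 2 groups).
#' @param n_perm number of permutations (default 999) or `"exhaustive"`.
#' @param seed RNG seed for random permutations.
#' @param strata optional factor restricting permutations.
#' @return object of class `permanova`: list with `pseudo_F`, `R2`, `p`,
#'   `n_perm`, `df_between`, `df_within`, `ss_between`, `ss_within`,
#'   `ss_total`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L, strata = NULL) {
  D <- as.matrix(d)
  if (!isSymmetric(unname(D)) || any(diag(D) != 0))
    stop_phantax("d must be a symmetric distance matrix with zero diagonal",
                 "validation_error")
  n <- nrow(D)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != n)
    stop_phantax("groups length must match the number of samples",
                 "validation_error")
  k <- nlevels(groups)
  if (k < 2) stop_phantax("need >= 2 groups", "validation_error")
  D2 <- D^2
  sst <- sum(D2) / (2 * n)
  ssw <- ss_within(D2, groups)
  ssb <- sst - ssw
  df_b <- k - 1
  df_w <- n - k
  f_of <- function(w) if (w > 0) (ssb_of(w) / df_b) / (w / df_w) else Inf
  ssb_of <- function(w) sst - w
  F_obs <- f_of(ssw)

  perm_F <- function(idx) {
    w <- ss_within(D2, groups[idx])
    if (w > 0) ((sst - w) / df_b) / (w / df_w) else Inf
  }
  if (identical(n_perm, "exhaustive")) {
    idxs <- all_label_permutations(n)
    Fs <- vapply(idxs, perm_F, 1.0)
    p <- mean(Fs >= F_obs - 1e-12)
    np <- length(idxs)
  } else {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      idx <- if (is.null(strata)) sample.int(n) else {
        out <- seq_len(n)
        for (s in unique(strata)) {
          w <- which(strata == s)
          out[w] <- w[sample.int(length(w))]
        }
        out
      }
      if (perm_F(idx) >= F_obs - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_perm)
    np <- n_perm
  }
  structure(list(pseudo_F = F_obs, R2 = ssb / sst, p = p, n_perm = np,
                 df_between = df_b, df_within = df_w,
                 ss_between = ssb, ss_within = ssw, ss_total = sst),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("Permutation PERMANOVA\n")
  cat(sprintf("  pseudo-F = %.4g on (%d, %d) df;  R2 = %.4g;  p = %.4g (%s permutations)\n",
              x$pseudo_F, x$df_between, x$df_within, x$R2, x$p,
              format(x$n_perm)))
  invisible(x)
}

#' Principal coordinates analysis
#'
#' Gower double-centering and eigendecomposition of a distance matrix.
#' Axes with positive eigenvalues are retained; negative eigenvalues are
#' reported, not corrected.
#'
#' @param d `dist` or symmetric distance matrix.
#' @return list with `points` (samples x positive axes, scaled so squared
#'   distances are reproduced on Euclidean-embeddable input), `eig` (all
#'   eigenvalues), `negative` (the negative ones).
#' @export
pcoa <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 2) stop_phantax("need >= 2 samples", "validation_error")
  fit <- suppressWarnings(stats::cmdscale(D, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  pts <- fit$points[, seq_along(pos), drop = FALSE]
  rownames(pts) <- rownames(D)
  list(points = pts, eig = eig, negative = eig[eig < 0])
}

#' Partial constrained ordination of a distance matrix
#'
#' Distance-based redundancy analysis with conditioning: PCoA coordinates
#' are residualized on the conditioning design matrix (least squares), the
#' residuals are regressed on the constraint matrix, and the fitted values
#' are eigen-analyzed. Used to display treatment structure after
#' partialling out mesocosm identity.
#'
#' @param d distance matrix.
#' @param constraints numeric model matrix (samples x constraint
#'   variables); factors should be expanded with [stats::model.matrix()].
#' @param conditioned_vars optional numeric model matrix to partial out.
#' @return list with `axes` (constrained sample scores), `eig`
#'   (constrained eigenvalues), and `inertia`, the fractions
#'   (`conditioned`, `constrained`, `unconstrained`) of retained
#'   (positive-eigenvalue) inertia, summing to 1.
#' @export
partial_constrained_ordination <- function(d, constraints,
                                           conditioned_vars = NULL) {
  pc <- pcoa(d)
  Y <- pc$points
  n <- nrow(Y)
  center <- function(M) sweep(M, 2, colMeans(M))
  total <- sum(Y^2)
  project <- function(Y, X) {
    X <- center(as.matrix(X))
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      warning("collinear columns reduced the model rank")
    qr.fitted(qrX, Y)
  }
  cond_inertia <- 0
  if (!is.null(conditioned_vars)) {
    fit_c <- project(Y, conditioned_vars)
    cond_inertia <- sum(fit_c^2)
    Y <- Y - fit_c
  }
  fit <- project(Y, constraints)
  constr_inertia <- sum(fit^2)
  resid_inertia <- sum((Y - fit)^2)
  sv <- svd(fit)
  keep <- sv$d^2 > sqrt(.Machine$double.eps) * max(sv$d^2, 1)
  axes <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
  rownames(axes) <- rownames(pc$points)
  list(axes = axes, eig = sv$d[keep]^2 / (n - 1),
       inertia = c(conditioned = cond_inertia / total,
                   constrained = constr_inertia / total,
                   unconstrained = resid_inertia / total))
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-squared p-value on k - 1 degrees
#' of freedom; validates the grouping and delegates to the standard test.
#'
#' @param values numeric response.
#' @param groups grouping factor with >= 2 groups.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2)
    stop_phantax("need >= 2 groups", "validation_error")
  if (stats::var(values) == 0) {
    return(list(H = 0, df = nlevels(groups) - 1, p = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
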