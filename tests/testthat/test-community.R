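test_that("richness and inverse Simpson match hand values and identities", {
  expect_equal(richness(c(5, 5, 5, 5)), 4L)
  expect_equal(inverse_simpson(c(5, 5, 5, 5)), 4.0)
  expect_equal(richness(c(10, 0, 0)), 1L)
  expect_equal(inverse_simpson(c(10, 0, 0)), 1.0)
  expect_equal(inverse_simpson(c(3, 1)), 1.6)
  expect_error(inverse_simpson(c(0, 0)), class = "validation_error")
  # a uniform S-taxon community has inverse Simpson exactly S
  for (S in c(1:10, 25, 50, 100))
    expect_equal(inverse_simpson(rep(7, S)), S)
})

test_that("Bray-Curtis matches hand arithmetic and vegan", {
  x <- make_counts(matrix(c(2L, 2L, 1L, 3L, 1L, 0L, 0L, 1L), 2, 4))
  d <- as.matrix(bray_curtis(x))
  expect_equal(d["s1", "s2"], 0.25)     # |2-1| + |2-3| over 8
  expect_equal(d["s3", "s4"], 1)        # disjoint samples
  expect_true(all(diag(d) == 0))
  skip_if_not_installed("vegan")
  big <- random_counts(25, 8, lambda = 6, seed = 17)
  expect_equal(as.matrix(bray_curtis(big)),
               as.matrix(vegan::vegdist(t(big), method = "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
  # rarefied equal-depth counts: count and relative-abundance forms agree
  r <- rarefy(big + 5L, depth = 40, seed = 1)
  rel <- sweep(r, 2, colSums(r), "/")
  expect_equal(as.matrix(bray_curtis(r)), as.matrix(bray_curtis_rel <- {
    n <- ncol(rel); m <- matrix(0, n, n, dimnames = list(colnames(rel), colnames(rel)))
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
      m[i, j] <- m[j, i] <- sum(abs(rel[, i] - rel[, j])) / 2
    m
  }), tolerance = 1e-12)
})

test_that("PERMANOVA reproduces the 4-point line oracle exactly", {
  d <- dist(c(0, 1, 3, 4))
  attr(d, "Labels") <- paste0("s", 1:4)
  g <- c("a", "a", "b", "b")
  res <- permanova(d, g, n_perm = "exhaustive")
  # hand arithmetic on the six pairwise distances:
  # SS_total = 40/4 = 10, SS_within = 1, pseudo-F = 9 / (1/2) = 18
  expect_equal(res$ss_total, 10)
  expect_equal(res$ss_within, 1)
  expect_equal(res$pseudo_F, 18)
  expect_equal(res$R2, 0.9)
  # brute force over the 3 distinct 2+2 partitions: only the observed one
  # reaches F = 18, so the exhaustive p is 1/3
  expect_equal(res$p, 1 / 3)
})

test_that("PERMANOVA agrees with an independent implementation on random data", {
  skip_if_not_installed("vegan")
  for (seed in 1:4) {
    x <- random_counts(6, 8, lambda = 30, seed = seed)
    g <- rep(c("a", "b"), each = 4)
    d <- bray_curtis(x)
    mine <- permanova(d, g, n_perm = "exhaustive")
    ref <- vegan::adonis2(d ~ g, permutations = 999)
    expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
    expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)
    expect_equal(mine$df_between, ref$Df[1])
    expect_equal(mine$df_within, ref$Df[2])
  }
})

test_that("PERMANOVA permutation machinery is seeded and respects strata", {
  x <- random_counts(5, 12, lambda = 20, seed = 23)
  g <- rep(c("a", "b"), 6)
  strata <- rep(1:3, each = 4)
  d <- bray_curtis(x)
  r1 <- permanova(d, g, n_perm = 99, seed = 5)
  r2 <- permanova(d, g, n_perm = 99, seed = 5)
  expect_identical(r1$p, r2$p)
  r3 <- permanova(d, g, n_perm = 99, seed = 5, strata = strata)
  expect_true(r3$p > 0 && r3$p <= 1)
  expect_error(permanova(d, rep("a", 12)), class = "validation_error")
})

test_that("PERMANOVA holds its size under an exchangeable null", {
  set.seed(99)
  hits <- 0
  nsim <- 400
  for (i in seq_len(nsim)) {
    x <- make_counts(matrix(rpois(5 * 10, 20), 5, 10))
    p <- permanova(bray_curtis(x), rep(c("a", "b"), each = 5),
                   n_perm = 99, seed = i)$p
    if (p <= 0.05) hits <- hits + 1
  }
  rate <- hits / nsim
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("PCoA embeds distances and reports degenerate spectra", {
  pts <- c(0, 2, 5)
  d <- dist(pts)
  attr(d, "Labels") <- paste0("s", 1:3)
  fit <- pcoa(d)
  # collinear points: one positive axis recovering distances up to sign
  expect_equal(ncol(fit$points), 1L)
  expect_equal(as.matrix(dist(fit$points)), as.matrix(d),
               tolerance = 1e-9, ignore_attr = TRUE)
  # zero distances: no positive eigenvalues
  z <- matrix(0, 3, 3, dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  fz <- pcoa(z)
  expect_equal(max(abs(fz$eig)), 0, tolerance = 1e-12)
  # Euclidean-embeddable input reconstructs distances from retained axes
  y <- matrix(rnorm(24), 8, 3)
  rownames(y) <- paste0("s", 1:8)
  fy <- pcoa(dist(y))
  expect_true(sum(fy$eig[fy$eig > 0]) >= 0)
  expect_equal(as.matrix(dist(fy$points)), as.matrix(dist(y)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("partial constrained ordination partitions inertia sensibly", {
  set.seed(31)
  y <- matrix(rnorm(40), 20, 2)
  rownames(y) <- paste0("s", 1:20)
  d <- dist(y)
  trt <- factor(rep(letters[1:4], 5))
  mes <- factor(rep(1:5, each = 4))
  X <- stats::model.matrix(~trt)[, -1]
  Z <- stats::model.matrix(~mes)[, -1]
  res <- partial_constrained_ordination(d, X, Z)
  expect_equal(sum(res$inertia), 1, tolerance = 1e-9)
  expect_true(all(res$inertia >= -1e-12))

  # constraints orthogonal to the coordinates: ~no constrained inertia
  fit <- pcoa(d)
  resid_orth <- qr.resid(qr(cbind(1, fit$points)), rnorm(20))
  r2 <- partial_constrained_ordination(d, matrix(resid_orth))
  expect_lt(r2$inertia["constrained"], 1e-9)

  # conditioning variables spanning the coordinates leave no residual
  r3 <- partial_constrained_ordination(d, X, conditioned_vars = fit$points)
  expect_lt(r3$inertia["constrained"] + r3$inertia["unconstrained"], 1e-9)

  # without conditioning, equals the direct constrained analysis
  r4 <- partial_constrained_ordination(d, X)
  r5 <- partial_constrained_ordination(d, X, conditioned_vars = NULL)
  expect_equal(r4$inertia, r5$inertia)

  skip_if_not_installed("vegan")
  ref <- vegan::dbrda(d ~ trt + Condition(mes))
  expect_equal(unname(res$inertia["conditioned"]),
               ref$pCCA$tot.chi / ref$tot.chi, tolerance = 1e-6)
  expect_equal(unname(res$inertia["constrained"]),
               ref$CCA$tot.chi / ref$tot.chi, tolerance = 1e-6)
})

test_that("Kruskal-Wallis matches hand ranks and is rank-invariant", {
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$H, 3.857, tolerance = 1e-3)
  expect_equal(res$df, 1)
  # identical groups
  expect_equal(kruskal_wallis(rep(5, 6), rep(c("a", "b"), each = 3))$H, 0)
  # invariance under monotone transformation
  set.seed(3)
  v <- rnorm(30); g <- rep(letters[1:3], 10)
  expect_equal(kruskal_wallis(v, g)$H, kruskal_wallis(exp(v), g)$H,
               tolerance = 1e-12)
})
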