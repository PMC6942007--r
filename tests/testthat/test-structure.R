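test_that("PCA recovers planted two-group structure", {
  tg <- planted_two_groups()
  pcs <- suppressWarnings(compute_pcs(tg$X, k = 5))
  expect_gt(abs(cor(pcs$scores[, 1], tg$a)), 0.99)
  # orthonormal loadings, descending eigenvalues
  expect_equal(crossprod(pcs$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pcs$eigenvalues) <= 1e-8))
})

test_that("PCA contracts: scores, duplication, degenerate input", {
  p <- tiny_params()
  X <- make_cohort(p)$genotypes
  pcs <- compute_pcs(X, k = 4)
  # scores equal standardized genotypes times loadings
  Z <- scale(X[, pcs$kept_snps])
  expect_equal(unname(pcs$scores), unname(Z %*% pcs$loadings),
               tolerance = 1e-8)

  # duplicating a dataset row duplicates its score row
  Xd <- rbind(X, X[3, ])
  pd <- compute_pcs(Xd, k = 3)
  expect_equal(pd$scores[nrow(Xd), ], pd$scores[3, ], tolerance = 1e-8)

  # monomorphic columns dropped with warning; all-monomorphic errors
  Xm <- cbind(X, 0L)
  expect_warning(pm <- compute_pcs(Xm, k = 3), "monomorphic")
  expect_false((ncol(X) + 1L) %in% pm$kept_snps)
  expect_error(compute_pcs(matrix(1L, 10, 4), k = 2), "monomorphic")
  expect_error(compute_pcs(X, k = 1000), "rank")
})

test_that("PC scores are equivariant under row permutation", {
  p <- tiny_params(seed = 55)
  X <- make_cohort(p)$genotypes
  perm <- sample(nrow(X))
  p1 <- compute_pcs(X, k = 3)
  p2 <- compute_pcs(X[perm, ], k = 3)
  expect_equal(p2$scores, p1$scores[perm, ], tolerance = 1e-6)
})

test_that("projection into a trained PC basis is consistent", {
  p <- sim_params(n_individuals = 200, n_snps = 250, sigma_p2 = 0.1,
                  seed = 61)
  train <- make_cohort(p)
  pcs <- suppressWarnings(compute_pcs(train$genotypes, k = 5))
  self <- project_pcs(pcs, train$genotypes)
  expect_equal(unname(self), unname(pcs$scores), tolerance = 1e-8)

  # new same-model individuals land in the training score range
  test <- make_cohort(p, freqs = train$freqs, arch = train$arch, rep = 1)
  s_new <- project_pcs(pcs, test$genotypes)[, 1]
  span <- range(pcs$scores[, 1])
  pad <- 0.5 * diff(span)
  expect_gt(mean(s_new > span[1] - pad & s_new < span[2] + pad), 0.95)

  expect_error(project_pcs(pcs, train$genotypes[, 1:10]), "SNPs")
})

test_that("detectability implements the phase-transition criterion", {
  d <- detectability(n = 2000, L = 4000, fst = 0.01)
  expect_true(d$detectable)
  expect_equal(d$statistic, 0.01 * sqrt(8e6))
  expect_equal(d$n_required, ceiling(1 / (0.01^2 * 4000)))

  d0 <- detectability(n = 1e6, L = 1e6, fst = 0)
  expect_false(d0$detectable)
  expect_identical(d0$n_required, Inf)

  # n_required non-increasing in L and fst
  nr <- function(L, fst) detectability(100, L, fst)$n_required
  expect_true(all(diff(sapply(c(100, 1000, 10000), nr, fst = 0.01)) <= 0))
  expect_true(all(diff(sapply(c(0.005, 0.01, 0.05), nr, L = 1000)) <= 0))
})

test_that("Hudson FST: fixation, identity, and generative oracle", {
  # complete fixation
  X <- rbind(matrix(1L, 10, 20), matrix(0L, 10, 20))
  expect_equal(empirical_fst(X, rep(1:2, each = 10)), 1)

  # identical underlying frequencies: FST near 0 (clamped at 0)
  p <- tiny_params(n_individuals = 600, sigma_p2 = 0, s = 0, seed = 71)
  co <- make_cohort(p)
  expect_lt(empirical_fst(co$genotypes, rep(1:2, 300)), 0.01)

  # oracle: plug-in Hudson on the true generative frequencies
  p <- sim_params(n_individuals = 2000, n_snps = 400, sigma_p2 = 0.05,
                  s = 0, seed = 72)
  anc <- draw_ancestral_freqs(p)
  arch <- assign_architecture(p, anc)
  fr <- draw_population_freqs(p, anc, arch)
  a <- rep(c(0, 1), each = 1000)           # pure-population individuals
  X <- sample_genotypes(a, fr, p)
  est <- empirical_fst(X, a)
  den <- fr$pop1 * (1 - fr$pop2) + fr$pop2 * (1 - fr$pop1)
  truth <- sum(((fr$pop1 - fr$pop2)^2)[den > 0]) / sum(den[den > 0])
  expect_lt(abs(est - truth), 0.1 * truth)

  expect_error(empirical_fst(X, c(1, rep(2, 1999))), "at least 2")
  expect_error(empirical_fst(X, rep(1, 2000)), "two groups")
})

test_that("structure becomes easier to see as N grows", {
  ns <- c(150, 400, 1100)
  mean_cor <- sapply(ns, function(n) {
    mean(sapply(1:2, function(r) {
      p <- sim_params(n_individuals = n, n_snps = 300, sigma_p2 = 0.1,
                      seed = 80 + r)
      co <- make_cohort(p)
      pcs <- suppressWarnings(compute_pcs(co$genotypes, k = 2))
      abs(cor(pcs$scores[, 1], co$admixture))
    }))
  })
  expect_true(all(diff(mean_cor) > -0.02))
  expect_gt(mean_cor[3], mean_cor[1])
})

test_that("reference SVD basis: self-projection, ordering, planted rank", {
  sm <- synth_sharing_matrix(120, 6, concentration = 30, seed = 91)
  b <- fit_reference_basis(sm)
  expect_true(all(diff(b$singular_values) <= 1e-8))
  expect_equal(crossprod(b$right_vectors),
               diag(ncol(b$right_vectors)), tolerance = 1e-8,
               ignore_attr = TRUE)
  self <- project_cohort(b, sm)
  expect_equal(unname(self), unname(b$ref_scores), tolerance = 1e-8)

  # rank-1 planted sharing matrix
  r1 <- outer(runif(50, 1, 2), c(1, 2, 3, 4))
  b1 <- fit_reference_basis(r1)
  expect_lt(b1$singular_values[2] / b1$singular_values[1], 1e-8)

  # degenerate columns
  expect_warning(bz <- fit_reference_basis(cbind(sm$values, 5)),
                 "zero-variance")
  expect_equal(length(bz$labels), 6)
  expect_error(suppressWarnings(fit_reference_basis(cbind(1:5, 3))),
               "fewer than 2")
})

test_that("cohort projection: consistency, centering, separation, linearity", {
  gm <- rbind(c(10, 1), c(1, 10))
  ref <- synth_sharing_matrix(80, 2, concentration = 60, group_means = gm,
                              seed = 92)
  b <- fit_reference_basis(ref)

  # a cohort row equal to a reference row gets that row's scores
  one <- ref$values[5, , drop = FALSE]
  expect_equal(drop(project_cohort(b, one)), b$ref_scores[5, ],
               tolerance = 1e-8, ignore_attr = TRUE)
  # the column-mean row maps to the origin
  expect_equal(drop(project_cohort(b, t(colMeans(ref$values)))),
               rep(0, 2), tolerance = 1e-8, ignore_attr = TRUE)

  # maximally distinct group means: axis 1 separates the groups
  s1 <- b$ref_scores[, 1]
  expect_true(max(s1[ref$group == 1]) < min(s1[ref$group == 2]) ||
                min(s1[ref$group == 1]) > max(s1[ref$group == 2]))

  # linearity: projecting a convex combination of rows
  mix <- 0.3 * ref$values[1, ] + 0.7 * ref$values[2, ]
  expect_equal(drop(project_cohort(b, t(mix))),
               0.3 * b$ref_scores[1, ] + 0.7 * b$ref_scores[2, ],
               tolerance = 1e-8, ignore_attr = TRUE)

  bad <- synth_sharing_matrix(10, 3, seed = 93)
  expect_error(project_cohort(b, bad), "labels")
})

test_that("variance_explained matches a brute-force least-squares oracle", {
  set.seed(17)
  S <- matrix(rnorm(60 * 4), 60, 4)
  y <- drop(S %*% c(1, -2, 0, 0.5)) + rnorm(60)
  ve <- variance_explained(S, y)
  expect_equal(ve$r2, brute_force_r2(S, y), tolerance = 1e-10)

  # perfect single-column predictor
  expect_equal(variance_explained(S[, 1, drop = FALSE], S[, 1])$r2, 1)

  # independent noise: R^2 near its null expectation k/(n-1)
  set.seed(18)
  Sn <- matrix(rnorm(500 * 5), 500, 5)
  yn <- rnorm(500)
  expect_lt(variance_explained(Sn, yn)$r2, 4 * 5 / 499)

  # nested monotonicity
  r2k <- sapply(1:4, function(k)
    variance_explained(S[, 1:k, drop = FALSE], y)$r2)
  expect_true(all(diff(r2k) >= -1e-12))

  # collinear columns are dropped, not fatal
  vc <- variance_explained(cbind(S, S[, 1]), y)
  expect_equal(vc$r2, ve$r2, tolerance = 1e-10)
  expect_length(vc$dropped, 1)

  expect_error(variance_explained(matrix(rnorm(12), 3, 4), rnorm(3)),
               "observations")
})

test_that("2D kernel smoother honors the masking radius", {
  set.seed(21)
  pts <- matrix(runif(40), 20, 2)
  vals <- rep(2.5, 20)
  g <- kernel_smooth_2d(pts, vals, grid = 10, bandwidth = 0.1)
  expect_equal(g$z[!g$mask], rep(2.5, sum(!g$mask)), tolerance = 1e-12)

  # node farther than max_dist from every observation is masked
  g2 <- kernel_smooth_2d(matrix(c(0, 0), 1), 7,
                         grid = list(c(0, 0.5), c(0, 0.5)),
                         bandwidth = 0.2, max_dist = 0.03)
  expect_true(is.na(g2$z[2, 2]))
  expect_true(g2$mask[2, 2])
  # node at the observation reproduces it
  expect_equal(g2$z[1, 1], 7)

  expect_error(kernel_smooth_2d(pts, vals, bandwidth = 0), "bandwidth")
})
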