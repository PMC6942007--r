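test_that("admixture draws respect the truncated-normal contract", {
  # variance-zero limit: huge L_eff collapses onto a0
  p <- sim_params(n_individuals = 50, n_snps = 10, a0 = 0.5,
                  l_eff = 1e12, seed = 1)
  expect_equal(draw_admixture(p), rep(0.5, 50), tolerance = 1e-4)

  # boundary a0 gives sigma_a^2 = 0 and exact boundary values
  p0 <- sim_params(n_individuals = 20, n_snps = 10, a0 = 0, e = 0, seed = 1)
  expect_identical(draw_admixture(p0), rep(0, 20))

  # large-sample variance matches a0(1-a0)/L_eff (independent arithmetic)
  p <- sim_params(n_individuals = 1e5, n_snps = 10, seed = 2)
  a <- draw_admixture(p)
  target <- 0.4 * 0.6 / 20
  mc_tol <- 3 * target * sqrt(2 / (1e5 - 1))
  expect_lt(abs(var(a) - target), mc_tol)

  # clamping, not rejection: extreme parameters put mass exactly at 0/1
  px <- sim_params(n_individuals = 500, n_snps = 10, a0 = 0.5, l_eff = 1,
                   seed = 3)
  ax <- draw_admixture(px)
  expect_true(all(ax >= 0 & ax <= 1))
  expect_true(any(ax == 0) || any(ax == 1))
})

test_that("ancestral frequencies are Uniform(0.05, 0.5) and seeded", {
  p <- sim_params(n_individuals = 10, n_snps = 1e5, seed = 5)
  f <- draw_ancestral_freqs(p)
  expect_true(all(f >= 0.05 & f <= 0.5))
  expect_identical(f, draw_ancestral_freqs(p))  # seeding contract
  se <- (0.45 / sqrt(12)) / sqrt(1e5)
  expect_lt(abs(mean(f) - 0.275), 3 * se)
})

test_that("trait architecture: causal subset, bounded uniform effects", {
  p <- tiny_params(causal_fraction = 0.001)
  expect_error(assign_architecture(p, draw_ancestral_freqs(p)),
               "zero causal")

  p <- sim_params(n_individuals = 10, n_snps = 2e4, causal_fraction = 0.5,
                  seed = 6)
  anc <- rep(0.5, p$n_snps)
  arch <- assign_architecture(p, anc)
  expect_equal(sum(arch$causal_indicator), 1e4)
  expect_true(all(arch$effect_sizes[arch$causal_indicator == 0] == 0))
  causal_beta <- arch$effect_sizes[arch$causal_indicator == 1]
  expect_true(all(causal_beta >= 0 & causal_beta <= 0.25))
  # Uniform(0, 0.25): mean 0.125
  expect_lt(abs(mean(causal_beta) - 0.125), 3 * 0.25 / sqrt(12) / 100)
})

test_that("population frequencies: drift, selection shift, clamping", {
  p <- tiny_params(sigma_p2 = 0, s = 0)
  anc <- draw_ancestral_freqs(p)
  arch <- assign_architecture(p, anc)
  fr <- draw_population_freqs(p, anc, arch)
  expect_identical(fr$pop1, anc)
  expect_identical(fr$pop2, anc)

  # zero drift, s = 0.2: causal SNPs shift in Population 1 only
  p <- tiny_params(sigma_p2 = 0, s = 0.2)
  anc <- rep(0.3, p$n_snps)
  arch <- assign_architecture(p, anc)
  fr <- draw_population_freqs(p, anc, arch)
  causal <- arch$causal_indicator == 1
  expect_equal(fr$pop1[causal], rep(0.36, sum(causal)))
  expect_equal(fr$pop1[!causal], rep(0.30, sum(!causal)))
  expect_equal(fr$pop2, rep(0.30, p$n_snps))

  # strong drift fixes / loses alleles exactly
  p <- sim_params(n_individuals = 10, n_snps = 2000, sigma_p2 = 1, seed = 8)
  anc <- draw_ancestral_freqs(p)
  fr <- draw_population_freqs(p, anc, assign_architecture(p, anc))
  expect_true(all(fr$pop1 >= 0 & fr$pop1 <= 1))
  expect_true(any(fr$pop1 == 0) && any(fr$pop1 == 1))
})

test_that("genotypes are Bernoulli with admixture-mixed probabilities", {
  p <- tiny_params()
  fr0 <- manual_freqs(rep(0.3, 5), rep(0, 5), rep(0.7, 5))
  X <- sample_genotypes(rep(1, 10), fr0, p)
  expect_true(all(X == 0))
  fr1 <- manual_freqs(rep(0.3, 5), rep(1, 5), rep(0.7, 5))
  expect_true(all(sample_genotypes(rep(1, 10), fr1, p) == 1))

  # mixture probability a*p1 + (1-a)*p2 = 0.3
  L <- 2e4
  frm <- manual_freqs(rep(0.3, L), rep(0.2, L), rep(0.4, L))
  Xm <- sample_genotypes(rep(0.5, 5), frm, p)
  expect_lt(abs(mean(Xm) - 0.3), 3 * sqrt(0.3 * 0.7 / (5 * L)))
})

test_that("phenotype construction follows the mixture formula", {
  co <- make_cohort(tiny_params(h = 1))
  expect_equal(co$phenotype, co$genetic_component)
  co <- make_cohort(tiny_params(h = 0, e = 1))
  expect_equal(co$phenotype, co$environment)

  # environmental exposure has expected variance 1 at defaults
  co <- make_cohort(sim_params(n_snps = 300, seed = 12))
  expect_lt(abs(var(co$environment) - 1), 3 * sqrt(2 / 1999))

  # degenerate inputs
  p <- tiny_params(a0 = 0, e = 0.5)
  expect_error(make_cohort(p), "sigma_a = 0")
  p <- tiny_params()
  dead <- manual_freqs(rep(0.3, 200), rep(0, 200), rep(0, 200))
  arch <- assign_architecture(p, rep(0.3, 200))
  expect_error(make_cohort(p, freqs = dead, arch = arch), "zero variance")
})

test_that("genetic variance share matches the mixing-weight algebra", {
  # with no drift and no selection Y_G is independent of E, so
  # var share = h^2 / (h^2 + (1-h)^2 e^2 + (1-h)^2 (1-e)^2) = 2/3
  p <- sim_params(n_individuals = 2e4, n_snps = 400, sigma_p2 = 0, s = 0,
                  seed = 13)
  co <- make_cohort(p)
  share <- var(p$h * co$genetic_component) / var(co$phenotype)
  expect_lt(abs(share - 2 / 3), 0.03)
})

test_that("make_cohort is deterministic and reuses freqs/arch", {
  p <- tiny_params()
  c1 <- make_cohort(p)
  c2 <- make_cohort(p)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$phenotype, c2$phenotype)

  test_co <- make_cohort(p, freqs = c1$freqs, arch = c1$arch, rep = 1)
  expect_identical(test_co$arch$effect_sizes, c1$arch$effect_sizes)
  expect_false(identical(test_co$genotypes, c1$genotypes))

  # shared generative frequencies: per-SNP sample frequencies agree
  p <- sim_params(n_individuals = 500, n_snps = 300, seed = 14)
  a1 <- make_cohort(p)
  a2 <- make_cohort(p, freqs = a1$freqs, arch = a1$arch, rep = 1)
  f1 <- colMeans(a1$genotypes); f2 <- colMeans(a2$genotypes)
  expect_lt(mean((f1 - f2)^2), 3 * mean(f1 * (1 - f1)) * 2 / 500)
  expect_gt(cor(f1, f2), 0.8)

  expect_error(make_cohort(p, freqs = a1$freqs,
                           arch = manual_arch(rep(1L, 10), rep(0.1, 10))),
               "n_snps")
})

test_that("phenotype identity holds exactly on generated cohorts", {
  for (seed in c(21, 22, 23)) {
    p <- sim_params(n_individuals = 80, n_snps = 120,
                    h = runif(1), e = runif(1), seed = seed)
    co <- make_cohort(p)
    expect_equal(co$phenotype,
                 p$h * co$genetic_component +
                   (1 - p$h) * p$e * co$environment +
                   (1 - p$h) * (1 - p$e) * co$noise,
                 tolerance = 1e-12)
  }
})

test_that("decouple_environment breaks the ancestry-environment link", {
  p <- sim_params(n_individuals = 2000, n_snps = 200, seed = 31)
  co <- make_cohort(p)
  expect_gt(abs(cor(co$admixture, co$environment)), 0.9)

  z <- decouple_environment(co, mode = "zero")
  expect_equal(z$phenotype,
               0.5 * co$genetic_component + 0.25 * co$noise)

  pe <- decouple_environment(co, mode = "permute")
  expect_identical(sort(pe$environment), sort(co$environment))
  expect_lt(abs(cor(pe$admixture, pe$environment)), 0.1)
  expect_identical(pe$genotypes, co$genotypes)
  expect_identical(pe$genetic_component, co$genetic_component)

  co0 <- make_cohort(tiny_params(e = 0))
  expect_warning(decouple_environment(co0), "no-op")
})

test_that("no drift + no selection means no structure in genotypes", {
  p <- sim_params(n_individuals = 2000, n_snps = 1000, sigma_p2 = 0,
                  s = 0, seed = 41)
  co <- make_cohort(p)
  grp <- co$admixture > median(co$admixture)
  n1 <- sum(grp); n2 <- sum(!grp)
  p1 <- colMeans(co$genotypes[grp, ]); p2 <- colMeans(co$genotypes[!grp, ])
  pp <- colMeans(co$genotypes)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  reject <- mean(abs(z) > 1.96)
  expect_gt(reject, 0.02)
  expect_lt(reject, 0.09)
})

test_that("draws stay in bounds for arbitrary parameters", {
  set.seed(99)
  for (i in 1:5) {
    p <- sim_params(n_individuals = 60, n_snps = 80,
                    a0 = runif(1), l_eff = runif(1, 0.5, 50),
                    sigma_p2 = runif(1, 0, 2), s = runif(1, -1, 2),
                    e = 0, seed = 500 + i)
    a <- draw_admixture(p)
    expect_true(all(a >= 0 & a <= 1))
    anc <- draw_ancestral_freqs(p)
    expect_true(all(anc >= 0.05 & anc <= 0.5))
    fr <- draw_population_freqs(p, anc, assign_architecture(p, anc))
    expect_true(all(fr$pop1 >= 0 & fr$pop1 <= 1))
    expect_true(all(fr$pop2 >= 0 & fr$pop2 <= 1))
  }
})

test_that("synthetic sharing matrices behave like painting output", {
  gm <- rbind(c(8, 1, 1), c(1, 8, 1), c(1, 1, 8))
  sm <- synth_sharing_matrix(60, 3, concentration = 40, group_means = gm,
                             seed = 4)
  expect_equal(dim(sm$values), c(60, 3))
  expect_equal(rowSums(sm$values), rep(100, 60))
  expect_true(all(sm$values >= 0))

  smi <- synth_sharing_matrix(9, 3, concentration = Inf, group_means = gm,
                              seed = 4)
  expect_equal(smi$values[1, ], 100 * gm[1, ] / sum(gm[1, ]))
  expect_equal(smi$values, smi$values[rep(1:3, 3), ])

  expect_error(synth_sharing_matrix(10, 3, concentration = 0), "> 0")
  expect_error(synth_sharing_matrix(10, 1), "K >= 2")
})
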