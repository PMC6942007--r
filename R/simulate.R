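#' Draw admixture fractions
#'
#' Admixture fractions from Population 1 are drawn from a truncated normal
#' `TruncNorm(a0, sigma_a^2)` with `sigma_a^2 = a0 * (1 - a0) / l_eff`, the
#' variance expected under binomial sampling of `l_eff` ancestry "loci".
#' Truncation is implemented by clamping normal draws to `[0, 1]` (not by
#' rejection), so probability mass can sit exactly at 0 and 1 — individuals
#' of pure ancestry are possible.
#'
#' @param params A [sim_params()] object (supplies `a0`, `l_eff`, `seed`).
#' @param n Number of individuals to draw (default `params$n_individuals`).
#' @param rep Replicate index for the RNG substream; cohorts drawn with
#'   different `rep` under one master seed are independent.
#' @return Numeric vector of length `n` with values in `[0, 1]`.
#' @export
draw_admixture <- function(params, n = params$n_individuals, rep = 0L) {
  stopifnot(inherits(params, "sim_params"), n >= 1)
  sd_a <- sqrt(params$sigma_a2)
  with_substream(params$seed, "admixture", rep, {
    a <- stats::rnorm(n, mean = params$a0, sd = sd_a)
    pmin(pmax(a, 0), 1)
  })
}

#' Draw ancestral allele frequencies
#'
#' One `Uniform(0.05, 0.5)` draw per SNP: the allele frequencies in the
#' common ancestral population before drift and selection act.
#'
#' @inheritParams draw_admixture
#' @return Numeric vector of length `params$n_snps` in `[0.05, 0.5]`.
#' @export
draw_ancestral_freqs <- function(params, rep = 0L) {
  stopifnot(inherits(params, "sim_params"))
  with_substream(params$seed, "freqs", rep,
                 stats::runif(params$n_snps, 0.05, 0.5))
}

#' Assign the trait architecture
#'
#' A uniformly random subset of `round(causal_fraction * L)` SNPs is causal
#' (`c_l = 1`). Causal effect sizes are drawn
#' `beta_l ~ Uniform(0, beta0 * p_l * (1 - p_l))` — rarer alleles get
#' smaller maximal effects — and non-causal SNPs have `beta_l = 0` exactly.
#'
#' @inheritParams draw_admixture
#' @param ancestral Ancestral frequency vector from [draw_ancestral_freqs()].
#' @return A `trait_architecture` list with `causal_indicator` (0/1 vector)
#'   and `effect_sizes` (nonnegative vector), both length L.
#' @export
assign_architecture <- function(params, ancestral, rep = 0L) {
  stopifnot(inherits(params, "sim_params"),
            length(ancestral) == params$n_snps)
  L <- params$n_snps
  n_causal <- round(params$causal_fraction * L)
  if (n_causal < 1)
    stop("causal_fraction * n_snps rounds to zero causal SNPs; ",
         "need n_snps * causal_fraction >= 0.5 so that at least one SNP ",
         "is causal", call. = FALSE)
  with_substream(params$seed, "architecture", rep, {
    idx <- sample.int(L, n_causal)
    c_l <- integer(L)
    c_l[idx] <- 1L
    beta <- numeric(L)
    beta[idx] <- stats::runif(n_causal) * params$beta0 *
      ancestral[idx] * (1 - ancestral[idx])
    structure(list(causal_indicator = c_l, effect_sizes = beta),
              class = "trait_architecture")
  })
}

#' Draw population allele frequencies
#'
#' Population frequencies drift away from the ancestral value:
#' `p_lm ~ TruncNorm(mean_lm, p_l * (1 - p_l) * sigma_p2)` clamped to
#' `[0, 1]`, so drift can fix or lose alleles. The selection-like shift
#' acts on Population 1 only: causal SNPs have mean `p_l * (1 + s)` there,
#' while Population 2 keeps mean `p_l`. This plants a genetic association
#' between the trait and ancestry.
#'
#' @inheritParams draw_admixture
#' @param ancestral Ancestral frequencies `p_l`.
#' @param arch A `trait_architecture` (supplies the causal indicator).
#' @return A `frequency_model` list with `ancestral`, `pop1`, `pop2`.
#' @export
draw_population_freqs <- function(params, ancestral, arch, rep = 0L) {
  stopifnot(inherits(params, "sim_params"),
            inherits(arch, "trait_architecture"),
            length(ancestral) == params$n_snps)
  if (params$sigma_p2 < 0) stop("sigma_p2 must be >= 0", call. = FALSE)
  L <- params$n_snps
  sd_p <- sqrt(ancestral * (1 - ancestral) * params$sigma_p2)
  m1 <- ancestral * (1 + arch$causal_indicator * params$s)
  with_substream(params$seed, "popfreqs", rep, {
    pop1 <- pmin(pmax(stats::rnorm(L, m1, sd_p), 0), 1)
    pop2 <- pmin(pmax(stats::rnorm(L, ancestral, sd_p), 0), 1)
    structure(list(ancestral = ancestral, pop1 = pop1, pop2 = pop2),
              class = "frequency_model")
  })
}

#' Sample genotypes
#'
#' Each genotype is one Bernoulli draw with success probability
#' `a_i * p_l1 + (1 - a_i) * p_l2`: the individual's own admixture-weighted
#' allele frequency. SNPs are independent given ancestry (no linkage
#' disequilibrium within populations), and dosages are 0/1.
#'
#' @param admixture Admixture-fraction vector `a_i`.
#' @param freqs A `frequency_model`.
#' @param params A [sim_params()] object (seed source).
#' @param rep RNG substream replicate index.
#' @param diploid If `TRUE`, draw two alleles per cell (dosages in
#'   `{0, 1, 2}`); the model's default is a single Bernoulli draw.
#' @return Integer N x L matrix with entries in `{0, 1}` (`{0, 1, 2}`
#'   when `diploid`).
#' @export
sample_genotypes <- function(admixture, freqs, params, rep = 0L,
                             diploid = FALSE) {
  stopifnot(inherits(freqs, "frequency_model"),
            inherits(params, "sim_params"))
  n <- length(admixture)
  L <- length(freqs$pop1)
  # per-cell mixture probability; rows are individuals
  prob <- outer(admixture, freqs$pop1) + outer(1 - admixture, freqs$pop2)
  if (any(prob < -1e-12) || any(prob > 1 + 1e-12))
    stop("internal error: genotype probability outside [0, 1]")
  prob <- pmin(pmax(prob, 0), 1)
  with_substream(params$seed, "genotypes", rep, {
    X <- matrix(as.integer(stats::runif(n * L) < prob), n, L)
    if (diploid)
      X <- X + matrix(as.integer(stats::runif(n * L) < prob), n, L)
    X
  })
}

#' Build phenotype components
#'
#' The raw polygenic score `sum_l X_il * beta_l` is standardized to sample
#' mean 0 and variance 1 (denominator N - 1).  The environmental exposure is
#' the standardized admixture fraction `E_i = (a_i - a0) / sigma_a`, which
#' has expected variance 1 by construction; it is the "environment follows
#' ancestry" confounder.  The phenotype is the fixed mixture
#' `Y = h * Y_G + (1 - h) * e * E + (1 - h) * (1 - e) * eps` with
#' `eps ~ Normal(0, 1)`.
#'
#' @param X Genotype matrix (N x L).
#' @param arch A `trait_architecture`.
#' @param admixture Admixture-fraction vector.
#' @param params A [sim_params()] object.
#' @param rep RNG substream replicate index (noise draw).
#' @return List with `genetic_component`, `environment`, `noise`,
#'   `phenotype`, all length N.
#' @export
build_phenotype <- function(X, arch, admixture, params, rep = 0L) {
  stopifnot(inherits(arch, "trait_architecture"),
            inherits(params, "sim_params"),
            nrow(X) == length(admixture),
            ncol(X) == length(arch$effect_sizes))
  yg_raw <- drop(X %*% arch$effect_sizes)
  v <- stats::var(yg_raw)
  if (!is.finite(v) || v <= 0)
    stop("genetic component has zero variance: no causal SNP segregates ",
         "in this cohort (increase N, causal_fraction, or allele ",
         "frequencies)", call. = FALSE)
  yg <- (yg_raw - mean(yg_raw)) / sqrt(v)
  sigma_a <- sqrt(params$sigma_a2)
  if (sigma_a == 0) {
    if (params$e > 0)
      stop("sigma_a = 0 (a0 at a boundary) but e > 0: the environmental ",
           "exposure (a - a0)/sigma_a is undefined", call. = FALSE)
    E <- numeric(length(admixture))
  } else {
    E <- (admixture - params$a0) / sigma_a
  }
  eps <- with_substream(params$seed, "noise", rep,
                        stats::rnorm(length(admixture)))
  y <- params$h * yg + (1 - params$h) * params$e * E +
    (1 - params$h) * (1 - params$e) * eps
  list(genetic_component = yg, environment = E, noise = eps, phenotype = y)
}

#' Simulate a complete cohort
#'
#' Runs the whole generative pipeline: admixture fractions, ancestral
#' frequencies, trait architecture, population frequencies, genotypes, and
#' phenotype components. When `freqs` and/or `arch` are supplied they are
#' reused unchanged — this is how test cohorts are drawn from the same
#' population as a training cohort (same frequencies and effect sizes, new
#' individuals; use a different `rep`).
#'
#' @inheritParams draw_admixture
#' @param freqs Optional `frequency_model` to reuse.
#' @param arch Optional `trait_architecture` to reuse.
#' @param diploid Draw two alleles per genotype (off by default; the
#'   model as stated uses 0/1 dosages).
#' @return A `cohort` object: list with `admixture`, `genotypes`,
#'   `genetic_component`, `environment`, `noise`, `phenotype`, plus the
#'   `freqs`, `arch`, `params` and `rep` that generated it.
#' @examples
#' p <- sim_params(n_individuals = 100, n_snps = 200, seed = 7)
#' train <- make_cohort(p)
#' test <- make_cohort(p, freqs = train$freqs, arch = train$arch, rep = 1)
#' identical(train$arch$effect_sizes, test$arch$effect_sizes)
#' @export
make_cohort <- function(params, freqs = NULL, arch = NULL, rep = 0L,
                        diploid = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  a <- draw_admixture(params, rep = rep)
  if (is.null(arch) || is.null(freqs)) {
    anc <- if (is.null(freqs)) draw_ancestral_freqs(params, rep = 0L)
           else freqs$ancestral
    if (is.null(arch)) arch <- assign_architecture(params, anc, rep = 0L)
    if (is.null(freqs))
      freqs <- draw_population_freqs(params, anc, arch, rep = 0L)
  }
  if (length(freqs$pop1) != params$n_snps ||
      length(arch$effect_sizes) != params$n_snps)
    stop("supplied freqs/arch do not match params$n_snps", call. = FALSE)
  X <- sample_genotypes(a, freqs, params, rep = rep, diploid = diploid)
  ph <- build_phenotype(X, arch, a, params, rep = rep)
  structure(c(list(admixture = a, genotypes = X), ph,
              list(freqs = freqs, arch = arch, params = params,
                   rep = as.integer(rep))),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d individuals x %d SNPs (%d causal)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              sum(x$arch$causal_indicator)))
  cat(sprintf("  admixture: mean %.3f, var %.4f; var(Y) = %.3f\n",
              mean(x$admixture), stats::var(x$admixture),
              stats::var(x$phenotype)))
  invisible(x)
}

#' Decouple the environment from ancestry
#'
#' Models "genes moved into a new environment": the environmental exposure
#' is permuted across individuals (destroying its association with
#' admixture while keeping its marginal distribution) or zeroed, and the
#' phenotype is rebuilt by the mixture formula with the original genetic
#' component and noise. Genotypes are untouched.
#'
#' @param cohort A `cohort` built with `e > 0`.
#' @param mode `"permute"` (default) or `"zero"`.
#' @return A modified `cohort`.
#' @export
decouple_environment <- function(cohort, mode = c("permute", "zero")) {
  stopifnot(inherits(cohort, "cohort"))
  mode <- match.arg(mode)
  p <- cohort$params
  if (p$e == 0) {
    warning("cohort was built with e = 0; decoupling is a no-op")
    return(cohort)
  }
  E <- switch(mode,
    permute = with_substream(p$seed, "decouple", cohort$rep,
                             sample(cohort$environment)),
    zero = numeric(length(cohort$environment)))
  cohort$environment <- E
  cohort$phenotype <- p$h * cohort$genetic_component +
    (1 - p$h) * p$e * E + (1 - p$h) * (1 - p$e) * cohort$noise
  cohort
}

#' Synthesize a haplotype-sharing matrix
#'
#' Emulates chromosome-painting output: each individual's row gives how
#' much of its genome it shares with each of `K` labeled reference
#' populations.  Individuals are assigned to groups; a row is drawn from a
#' Dirichlet distribution centered on its group's mean profile with the
#' given concentration (larger = tighter around the mean;
#' `concentration = Inf` returns the mean profile exactly), then scaled to
#' a fixed row total.  This is a synthetic stand-in for painting output —
#' it reproduces its compositional geometry, not the haplotype model.
#'
#' @param n Number of individuals.
#' @param K Number of reference populations (>= 2).
#' @param concentration Dirichlet concentration (> 0, may be `Inf`).
#' @param group_means Optional K x K nonnegative matrix; row g is the mean
#'   sharing profile of group g. Default: uniform background with a 3x
#'   self-sharing excess on the diagonal.
#' @param group Optional integer vector of group assignments in `1..K`;
#'   default cycles individuals through the groups evenly.
#' @param row_total Fixed row sum of the output (default 100, think
#'   "centimorgans shared").
#' @param seed Integer seed.
#' @return A `sharing_matrix`: list with `values` (n x K), `labels`,
#'   `group`, `row_total`.
#' @export
synth_sharing_matrix <- function(n, K, concentration = 50,
                                 group_means = NULL, group = NULL,
                                 row_total = 100, seed = 1L) {
  stopifnot(n >= 1, K >= 2)
  if (!is.finite(concentration) && !is.infinite(concentration))
    stop("concentration must be a positive real (possibly Inf)",
         call. = FALSE)
  if (concentration <= 0)
    stop("concentration must be > 0", call. = FALSE)
  if (is.null(group_means)) {
    group_means <- matrix(1, K, K)
    diag(group_means) <- 3
  }
  stopifnot(nrow(group_means) == K, ncol(group_means) == K,
            all(group_means >= 0), all(rowSums(group_means) > 0))
  group_means <- group_means / rowSums(group_means)
  if (is.null(group)) group <- rep_len(seq_len(K), n)
  stopifnot(length(group) == n, all(group %in% seq_len(K)))
  with_substream(seed, "sharing", 0L, {
    if (is.infinite(concentration)) {
      vals <- group_means[group, , drop = FALSE]
    } else {
      alpha <- concentration * group_means[group, , drop = FALSE]
      g <- matrix(stats::rgamma(n * K, shape = alpha), n, K)
      # guard rows that underflow to all-zero gamma draws
      zero <- rowSums(g) == 0
      if (any(zero)) g[zero, ] <- group_means[group[zero], , drop = FALSE]
      vals <- g / rowSums(g)
    }
    structure(list(values = vals * row_total,
                   labels = paste0("ref", seq_len(K)),
                   group = as.integer(group), row_total = row_total),
              class = "sharing_matrix")
  })
}
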