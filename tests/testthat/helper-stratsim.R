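# Shared fixtures, built in code.

# small default-shaped parameter set for fast unit tests
tiny_params <- function(...) {
  args <- list(n_individuals = 150, n_snps = 200, seed = 101L)
  args[names(list(...))] <- list(...)
  do.call(sim_params, args)
}

# a two-population cohort with a hard group split (a_i in {0, 1}) and
# strongly drifted frequencies: planted structure PCA must recover
planted_two_groups <- function(n = 200, L = 300, sigma_p2 = 0.5,
                               seed = 7L) {
  p <- sim_params(n_individuals = n, n_snps = L, sigma_p2 = sigma_p2,
                  s = 0, a0 = 0.5, seed = seed)
  a <- rep(c(0, 1), each = n / 2)
  anc <- draw_ancestral_freqs(p)
  arch <- assign_architecture(p, anc)
  freqs <- draw_population_freqs(p, anc, arch)
  X <- sample_genotypes(a, freqs, p)
  list(X = X, a = a, freqs = freqs, arch = arch, params = p)
}

# independent least-squares oracle: R^2 via a direct QR solve
brute_force_r2 <- function(scores, y) {
  M <- cbind(1, as.matrix(scores))
  beta <- qr.solve(M, y)
  1 - sum((y - M %*% beta)^2) / sum((y - mean(y))^2)
}

# hand-built frequency model / architecture for degenerate-input tests
manual_freqs <- function(ancestral, pop1, pop2) {
  structure(list(ancestral = ancestral, pop1 = pop1, pop2 = pop2),
            class = "frequency_model")
}
manual_arch <- function(causal, beta) {
  structure(list(causal_indicator = causal, effect_sizes = beta),
            class = "trait_architecture")
}
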