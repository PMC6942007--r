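#' Simulation parameters for the admixed-cohort generative model
#'
#' Bundles every constant of the generative model: an admixed population is
#' formed from two source populations, ancestry-linked drift and selection
#' shape allele frequencies, and the phenotype mixes a polygenic score, an
#' ancestry-linked environmental exposure, and independent noise.
#'
#' The defaults are the model's reference configuration:
#' `n_individuals = 2000`, `n_snps = 4000`, `l_eff = 20`, `a0 = 0.4`,
#' `beta0 = 1`, `s = 0.2`, `h = 0.5`, `e = 0.5`.  The drift scale
#' `sigma_p2 = 0.01` and `causal_fraction = 0.1` are package defaults and
#' freely configurable.
#'
#' @param n_individuals Number of individuals N.
#' @param n_snps Number of SNPs L.
#' @param l_eff Effective number of admixture "loci" L_eff; the admixture
#'   fraction has variance `a0 * (1 - a0) / l_eff`, so small values emulate
#'   recent admixture and large values ancient admixture.
#' @param a0 Mean admixture fraction from Population 1, in `[0, 1]`.
#' @param sigma_p2 Drift variance scale for population allele frequencies
#'   (frequency variance is `p * (1 - p) * sigma_p2`).
#' @param s Selection / extreme-drift shift: causal-SNP frequencies in
#'   Population 1 have mean `p * (1 + s)`. Must be >= -1.
#' @param beta0 Effect-size scale; causal effects are drawn
#'   `Uniform(0, beta0 * p * (1 - p))`.
#' @param h Genetic mixing weight ("heritability" weight), in `[0, 1]`.
#' @param e Environmental mixing weight, in `[0, 1]`.
#' @param causal_fraction Fraction of SNPs that are causal, in `(0, 1]`.
#' @param seed Master random seed (integer). Every stochastic stage draws
#'   from a substream derived deterministically from this seed, so stages
#'   can be re-run independently and cohorts are reproducible end to end.
#'
#' @return An object of class `sim_params` (a validated list) with the
#'   derived admixture variance `sigma_a2 = a0 * (1 - a0) / l_eff` attached.
#' @examples
#' p <- sim_params(n_individuals = 200, n_snps = 100, seed = 1)
#' p$sigma_a2
#' @export
sim_params <- function(n_individuals = 2000, n_snps = 4000, l_eff = 20,
                       a0 = 0.4, sigma_p2 = 0.01, s = 0.2, beta0 = 1,
                       h = 0.5, e = 0.5, causal_fraction = 0.1, seed = 1L) {
  p <- list(
    n_individuals = n_individuals, n_snps = n_snps, l_eff = l_eff,
    a0 = a0, sigma_p2 = sigma_p2, s = s, beta0 = beta0, h = h, e = e,
    causal_fraction = causal_fraction, seed = as.integer(seed)
  )
  validate_sim_params(p)
  p$sigma_a2 <- a0 * (1 - a0) / l_eff
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(p$n_individuals) && p$n_individuals >= 1, "n_individuals",
      "must be a positive count")
  chk(num1(p$n_snps) && p$n_snps >= 1, "n_snps", "must be a positive count")
  chk(num1(p$l_eff) && p$l_eff > 0, "l_eff", "must be a positive real")
  chk(num1(p$a0) && p$a0 >= 0 && p$a0 <= 1, "a0", "must lie in [0, 1]")
  chk(num1(p$sigma_p2) && p$sigma_p2 >= 0, "sigma_p2", "must be >= 0")
  chk(num1(p$s) && p$s >= -1, "s", "must be >= -1")
  chk(num1(p$beta0) && p$beta0 >= 0, "beta0", "must be >= 0")
  chk(num1(p$h) && p$h >= 0 && p$h <= 1, "h", "must lie in [0, 1]")
  chk(num1(p$e) && p$e >= 0 && p$e <= 1, "e", "must lie in [0, 1]")
  chk(num1(p$causal_fraction) && p$causal_fraction > 0 &&
        p$causal_fraction <= 1, "causal_fraction", "must lie in (0, 1]")
  chk(num1(p$seed), "seed", "must be a single integer")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (admixed two-population model)\n")
  cat(sprintf("  N = %d individuals, L = %d SNPs (causal fraction %.3g)\n",
              x$n_individuals, x$n_snps, x$causal_fraction))
  cat(sprintf("  admixture: a0 = %.3g, L_eff = %.3g (sigma_a^2 = %.4g)\n",
              x$a0, x$l_eff, x$sigma_a2))
  cat(sprintf("  drift sigma_p^2 = %.3g, selection shift s = %.3g, beta0 = %.3g\n",
              x$sigma_p2, x$s, x$beta0))
  cat(sprintf("  phenotype mix: h = %.3g, e = %.3g; master seed %d\n",
              x$h, x$e, x$seed))
  invisible(x)
}

#' Modify simulation parameters
#'
#' Returns a copy of `params` with the named fields replaced and all
#' invariants re-checked. Used by the scenario engines to apply
#' case-specific overrides.
#'
#' @param params A [sim_params()] object.
#' @param ... Named fields to replace.
#' @return A new `sim_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "sim_params"))
  repl <- list(...)
  keep <- setdiff(names(unclass(params)), "sigma_a2")
  base <- unclass(params)[keep]
  bad <- setdiff(names(repl), keep)
  if (length(bad)) stop("unknown parameter field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  base[names(repl)] <- repl
  do.call(sim_params, base)
}

# Deterministic substream seeds: every stochastic stage of the generator
# seeds R's RNG from a value derived from (master seed, stage, replicate),
# so any stage can be reproduced in isolation. Kept strictly below 2^31.
substream_seed <- function(seed, stage, rep = 0L) {
  stages <- c(admixture = 1, freqs = 2, architecture = 3, popfreqs = 4,
              genotypes = 5, noise = 6, decouple = 7, sharing = 8,
              outcome = 9, scenario = 10, mr = 11)
  if (!stage %in% names(stages)) stop("unknown RNG stage: ", stage)
  v <- (abs(as.double(seed)) * 48271 + stages[[stage]] * 1299721 +
          as.double(rep) * 9973) %% 2147483629
  as.integer(v)
}

with_substream <- function(seed, stage, rep, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, stage, rep))
  expr
}
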