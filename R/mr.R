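#' Per-SNP association summaries
#'
#' For each requested SNP, the ordinary least squares slope and standard
#' error from `trait ~ intercept + SNP + covariates`. Covariates are
#' residualized out once (Frisch-Waugh), so the per-SNP work is a scalar
#' regression; slopes and standard errors equal the full multiple
#' regression with degrees of freedom `n - n_covariates - 2`. SNPs that
#' are monomorphic or collinear with the covariates are dropped with a
#' warning.
#'
#' @param y Trait vector.
#' @param X Genotype matrix.
#' @param covariates Optional covariate matrix (e.g., PC scores).
#' @param snps Column indices of the SNPs to test (default all).
#' @return A `snp_summary` data frame: `snp_index`, `beta`, `se`, `z`,
#'   `n`, `corrected`, `k_pcs_used`.
#' @export
snp_summaries <- function(y, X, covariates = NULL,
                          snps = seq_len(ncol(X))) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(snps) >= 1)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 2)
    stop("need n > number of covariate columns + 2", call. = FALSE)
  W <- if (k == 0) matrix(1, n, 1) else cbind(1, as.matrix(covariates))
  qw <- qr(W)
  ry <- qr.resid(qw, y)
  G <- qr.resid(qw, X[, snps, drop = FALSE])
  ssx <- colSums(G^2)
  df <- n - ncol(W) - 1L
  ok <- ssx > 1e-10 * n
  if (!any(ok))
    stop("all requested SNPs are monomorphic or collinear with the ",
         "covariates", call. = FALSE)
  if (any(!ok))
    warning(sprintf("%d SNP(s) dropped: monomorphic or collinear with covariates",
                    sum(!ok)))
  beta <- colSums(G * ry) / ssx
  rss <- sum(ry^2) - beta^2 * ssx
  se <- sqrt(pmax(rss, 0) / df / ssx)
  out <- data.frame(snp_index = snps[ok], beta = beta[ok], se = se[ok],
                    z = beta[ok] / se[ok], n = n,
                    corrected = k > 0, k_pcs_used = k)
  class(out) <- c("snp_summary", "data.frame")
  out
}

#' Wald ratio instrumental-variable estimate
#'
#' The per-SNP causal estimate in two-sample Mendelian randomization:
#' `beta_iv = beta_outcome / beta_exposure`, with standard error by the
#' first-order delta method,
#' `se_iv^2 = se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4`.
#' Weak instruments make the ratio unstable, so the exposure association
#' must pass `|z| >= z_min` (default 3).
#'
#' @param exposure,outcome Single rows of a [snp_summaries()] table (or
#'   any list with `snp_index`, `beta`, `se`) for the same SNP, from the
#'   exposure and outcome samples respectively.
#' @param z_min Weak-instrument guard on `|beta_exp / se_exp|`.
#' @return An `mr_estimate`: `method = "wald"`, `beta_iv`, `se_iv`,
#'   `n_snps_used = 1`.
#' @export
wald_ratio <- function(exposure, outcome, z_min = 3) {
  if (!isTRUE(all.equal(exposure$snp_index, outcome$snp_index)))
    stop("exposure and outcome summaries refer to different SNPs",
         call. = FALSE)
  if (abs(exposure$beta / exposure$se) < z_min)
    stop(sprintf("weak instrument: exposure |z| = %.2f < %.2f",
                 abs(exposure$beta / exposure$se), z_min), call. = FALSE)
  b <- outcome$beta / exposure$beta
  se <- sqrt(outcome$se^2 / exposure$beta^2 +
               outcome$beta^2 * exposure$se^2 / exposure$beta^4)
  structure(list(method = "wald", beta_iv = b, se_iv = se,
                 n_snps_used = 1L), class = "mr_estimate")
}

#' Inverse-variance-weighted MR estimate
#'
#' Fixed-effect inverse-variance-weighted average of per-SNP Wald ratios:
#' weights `1 / se_ratio^2`, standard error `1 / sqrt(sum(weights))`.
#' SNPs failing the weak-instrument guard are dropped; with a single SNP
#' the result equals [wald_ratio()] exactly.
#'
#' @param exposures,outcomes [snp_summaries()] tables over matched SNPs
#'   from the exposure and outcome samples.
#' @param z_min Weak-instrument guard applied to the exposure z-score.
#' @return An `mr_estimate`: `method = "ivw"`, `beta_iv`, `se_iv`,
#'   `n_snps_used`.
#' @export
ivw <- function(exposures, outcomes, z_min = 3) {
  m <- merge(as.data.frame(exposures), as.data.frame(outcomes),
             by = "snp_index", suffixes = c("_exp", "_out"))
  if (nrow(m) == 0)
    stop("no SNPs shared between exposure and outcome summaries",
         call. = FALSE)
  m <- m[abs(m$beta_exp / m$se_exp) >= z_min, , drop = FALSE]
  if (nrow(m) == 0)
    stop("no instruments pass the weak-instrument guard (|z| >= ",
         z_min, ")", call. = FALSE)
  ratio <- m$beta_out / m$beta_exp
  se <- sqrt(m$se_out^2 / m$beta_exp^2 +
               m$beta_out^2 * m$se_exp^2 / m$beta_exp^4)
  w <- 1 / se^2
  if (nrow(m) == 1L) {   # exact Wald identity for a single instrument
    beta_iv <- ratio; se_iv <- se
  } else {
    beta_iv <- sum(w * ratio) / sum(w)
    se_iv <- 1 / sqrt(sum(w))
  }
  structure(list(method = "ivw", beta_iv = beta_iv, se_iv = se_iv,
                 n_snps_used = nrow(m)), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate (%s, %d SNP%s): beta = %.4f, se = %.4f, z = %.2f\n",
              x$method, x$n_snps_used, if (x$n_snps_used == 1) "" else "s",
              x$beta_iv, x$se_iv, x$beta_iv / x$se_iv))
  invisible(x)
}

#' Two-sample MR under differential structure correction
#'
#' The experiment behind the claim that unequal sample sizes can bias
#' two-sample Mendelian randomization through unequal ability to detect
#' (and so correct for) population structure.  Per replicate, one admixed
#' population of `n_exposure + n_outcome` individuals is simulated and
#' split into non-overlapping exposure and outcome samples. The exposure
#' is the simulated phenotype `T`; the outcome is
#' `O = gamma * T + delta * A + Normal(0, 1)`, where `A = (a - a0)/sigma_a`
#' is standardized ancestry — `delta > 0` is a direct ancestry-to-outcome
#' path that violates the MR assumptions unless both samples are corrected.
#' Causal SNPs are the instruments; per-sample GWAS (with each sample's own
#' PCs) feed an IVW estimate of `gamma`.
#'
#' Arms (samples are disjoint within every arm):
#' * `"uncorrected"` — unequal split (`n_exposure`, `n_outcome`), no PCs
#'   in either sample;
#' * `"equal_full"` — the same individuals re-split into two equal halves
#'   of `(n_exposure + n_outcome) / 2`, both corrected with `k_pcs` PCs:
#'   the benign design in which both samples have the same power to see
#'   structure;
#' * `"differential"` — unequal split with per-sample correction: with
#'   `pc_rule = "detect"` each sample keeps the PCs its own eigenvalues
#'   support (capped at `k_pcs`; see [n_detectable_pcs()]), so a sample
#'   under the detection threshold keeps fewer or none; with
#'   `pc_rule = "fixed_k"` the exposure sample uses `k_pcs` and the
#'   outcome sample `k_small` (a controlled contrast).
#'
#' @param params Base [sim_params()] (its `n_individuals` is overridden by
#'   `n_exposure + n_outcome`).
#' @param n_exposure,n_outcome Sample sizes (each >= 50).
#' @param gamma True causal effect of the exposure on the outcome.
#' @param delta Direct ancestry-to-outcome effect (confounding path).
#' @param pc_rule `"detect"` or `"fixed_k"` (governs the differential arm).
#' @param k_pcs PC count for full correction (default 20).
#' @param k_small PC count for the outcome sample under
#'   `pc_rule = "fixed_k"` (default 0).
#' @param arms Character subset of
#'   `c("uncorrected", "equal_full", "differential")`.
#' @param n_replicates Number of replicates.
#' @param seed Master seed (default `params$seed`).
#' @param z_min Weak-instrument guard passed to [ivw()].
#' @return An `mr_bias_table` data frame: one row per replicate x arm with
#'   `gamma_hat`, `se`, `bias` (`gamma_hat - gamma`), `n_snps_used`,
#'   `k_exposure`, `k_outcome`.
#' @export
two_sample_experiment <- function(params = sim_params(), n_exposure,
                                  n_outcome, gamma, delta,
                                  pc_rule = c("detect", "fixed_k"),
                                  k_pcs = 20, k_small = 0,
                                  arms = c("uncorrected", "equal_full",
                                           "differential"),
                                  n_replicates = 1, seed = params$seed,
                                  z_min = 3) {
  pc_rule <- match.arg(pc_rule)
  arms <- match.arg(arms, several.ok = TRUE)
  stopifnot(n_exposure >= 50, n_outcome >= 50, n_replicates >= 1)
  n_tot <- n_exposure + n_outcome
  n_half <- floor(n_tot / 2)
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    p_r <- update_params(params, n_individuals = n_tot,
                         seed = substream_seed(seed, "mr", r))
    co <- make_cohort(p_r, rep = 0L)
    A <- co$environment  # standardized ancestry (a - a0)/sigma_a
    noise <- with_substream(p_r$seed, "outcome", 0L, stats::rnorm(n_tot))
    O <- gamma * co$phenotype + delta * A + noise
    instruments <- which(co$arch$causal_indicator == 1L)

    one_fit <- function(idx_e, idx_o, k_e, k_o) {
      if (length(intersect(idx_e, idx_o)) > 0)
        stop("exposure and outcome samples overlap", call. = FALSE)
      Xe <- co$genotypes[idx_e, , drop = FALSE]
      Xo <- co$genotypes[idx_o, , drop = FALSE]
      if (identical(k_e, "detect")) k_e <- n_detectable_pcs(Xe, k_max = k_pcs)
      if (identical(k_o, "detect")) k_o <- n_detectable_pcs(Xo, k_max = k_pcs)
      # monomorphic drops are routine inside replicate loops; keep them quiet
      cov_e <- if (k_e > 0)
        suppressWarnings(compute_pcs(Xe, k = k_e)$scores) else NULL
      cov_o <- if (k_o > 0)
        suppressWarnings(compute_pcs(Xo, k = k_o)$scores) else NULL
      se_tab <- suppressWarnings(
        snp_summaries(co$phenotype[idx_e], Xe, covariates = cov_e,
                      snps = instruments))
      so_tab <- suppressWarnings(
        snp_summaries(O[idx_o], Xo, covariates = cov_o,
                      snps = instruments))
      est <- ivw(se_tab, so_tab, z_min = z_min)
      list(est = est, k_e = k_e, k_o = k_o)
    }

    idx_e <- seq_len(n_exposure)
    idx_o <- n_exposure + seq_len(n_outcome)
    arm_spec <- list(
      uncorrected = list(idx_e, idx_o, 0L, 0L),
      equal_full = list(seq_len(n_half),
                        n_half + seq_len(n_half), k_pcs, k_pcs),
      differential = if (pc_rule == "detect")
        list(idx_e, idx_o, "detect", "detect")
      else list(idx_e, idx_o, k_pcs, k_small))
    rows <- lapply(arms, function(arm) {
      f <- do.call(one_fit, arm_spec[[arm]])
      data.frame(replicate = r, arm = arm, gamma = gamma, delta = delta,
                 gamma_hat = f$est$beta_iv, se = f$est$se_iv,
                 bias = f$est$beta_iv - gamma,
                 n_snps_used = f$est$n_snps_used,
                 k_exposure = f$k_e, k_outcome = f$k_o,
                 stringsAsFactors = FALSE)
    })
    out[[r]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("mr_bias_table", "data.frame")
  res
}
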