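#' Case 1 / Case 2 prediction scenarios
#'
#' Runs the prediction experiment that contrasts uncorrected and
#' PC-corrected genomic prediction under two kinds of stratification:
#'
#' * **Case 1 — true genetic structure** (`s = 0.2`, `e = 0`): causal-SNP
#'   frequencies are shifted in Population 1, so the trait is genuinely
#'   genetically associated with ancestry. PC correction removes real
#'   signal and is expected to *reduce* test accuracy.
#' * **Case 2 — environmental confounding** (`s = 0`, `e = 0.5`): ancestry
#'   predicts the environment, not the causal genetics. The uncorrected
#'   predictor fits the environmental component through ancestry-informative
#'   SNPs, which looks good on a test cohort drawn from the same
#'   environment ("coupled") but inflates error once the environment is
#'   decoupled from ancestry; PC correction protects against this at the
#'   cost of apparent accuracy.
#'
#' Both cases raise the drift scale to `sigma_p2 = 0.1` (overridable via
#' `case_overrides`): the contrast between the arms requires ancestry to
#' be *detectable*, and at the package default `sigma_p2 = 0.01` the
#' admixture axis sits below the eigenvalue detection threshold at the
#' default N and L, making PC correction a no-op (see
#' [n_detectable_pcs()]).
#'
#' Per replicate: a training cohort is simulated; marker BLUPs are fitted
#' with no covariates (uncorrected) and with the top `k_pcs` training PCs
#' (corrected); a test cohort sharing the population frequencies and trait
#' architecture is simulated; both arms are scored on the coupled test
#' cohort and, for Case 2, on an environment-permuted (decoupled) copy.
#' Both fits share one eigendecomposition of the genotype kernel, and test
#' individuals are never used in training.
#'
#' @param params Base [sim_params()]; the case overrides are applied on
#'   top (and can themselves be overridden via `case_overrides`).
#' @param case_id 1 or 2.
#' @param n_replicates Number of independent replicates.
#' @param k_pcs Number of training PCs used in the corrected arm
#'   (`0` makes both arms identical).
#' @param seed Master seed for the experiment (default `params$seed`).
#' @param case_overrides Optional named list of parameter overrides
#'   applied after the case defaults.
#' @return A `scenario_result` data frame with one row per
#'   replicate x arm x regime: `case_id`, `replicate`, `arm`
#'   (`"uncorrected"`/`"pc_corrected"`), `test_regime`
#'   (`"coupled"`/`"decoupled"`), `accuracy_r`, `mse`, `r2`.
#' @examples
#' \donttest{
#' p <- sim_params(n_individuals = 300, n_snps = 400, seed = 5)
#' res <- run_scenario(p, case_id = 1, n_replicates = 3, k_pcs = 5)
#' summarize_scenario(res)
#' }
#' @export
run_scenario <- function(params = sim_params(), case_id, n_replicates,
                         k_pcs = 20, seed = params$seed,
                         case_overrides = NULL) {
  stopifnot(case_id %in% c(1, 2), n_replicates >= 1, k_pcs >= 0)
  ov <- if (case_id == 1) list(s = 0.2, e = 0, sigma_p2 = 0.1)
        else list(s = 0, e = 0.5, sigma_p2 = 0.1)
  if (!is.null(case_overrides)) ov[names(case_overrides)] <- case_overrides
  base <- do.call(update_params, c(list(params), ov))
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    p_r <- update_params(base, seed = substream_seed(seed, "scenario", r))
    train <- make_cohort(p_r, rep = 0L)
    test <- make_cohort(p_r, freqs = train$freqs, arch = train$arch,
                        rep = 1L)
    Xc <- sweep(train$genotypes, 2, colMeans(train$genotypes))
    decomp <- eigen(tcrossprod(Xc), symmetric = TRUE)
    fits <- list(
      uncorrected = fit_marker_blup(train$phenotype, train$genotypes,
                                    decomposition = decomp))
    if (k_pcs > 0) {
      # monomorphic drops are routine at high drift; keep replicate loops quiet
      pcs <- suppressWarnings(compute_pcs(train$genotypes, k = k_pcs))
      fits$pc_corrected <- fit_marker_blup(train$phenotype, train$genotypes,
                                           covariates = pcs$scores,
                                           decomposition = decomp)
    } else {
      fits$pc_corrected <- fits$uncorrected
    }
    regimes <- list(coupled = test)
    if (case_id == 2)
      regimes$decoupled <- decouple_environment(test, mode = "permute")
    rows <- list()
    for (arm in names(fits)) {
      pred <- lapply(regimes, function(co)
        predict_phenotype(fits[[arm]], co$genotypes))
      for (reg in names(regimes)) {
        acc <- evaluate_accuracy(pred[[reg]], regimes[[reg]]$phenotype)
        rows[[paste(arm, reg)]] <- data.frame(
          case_id = case_id, replicate = r, arm = arm, test_regime = reg,
          accuracy_r = acc$r, mse = acc$mse, r2 = acc$r2,
          stringsAsFactors = FALSE)
      }
    }
    out[[r]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("scenario_result", "data.frame")
  res
}

#' Summarize a scenario result table
#'
#' Per arm x regime means with Monte-Carlo standard errors, plus the
#' paired uncorrected-minus-corrected differences in accuracy and MSE per
#' regime with a one-sided sign-test p-value for "corrected accuracy is
#' lower".
#'
#' @param res A `scenario_result` from [run_scenario()].
#' @return List with `by_arm` (data frame of means and MC standard
#'   errors) and `paired` (data frame of per-regime paired contrasts).
#' @export
summarize_scenario <- function(res) {
  stopifnot(is.data.frame(res),
            all(c("arm", "test_regime", "accuracy_r", "mse") %in%
                  names(res)))
  mcse <- function(x) stats::sd(x) / sqrt(length(x))
  by_arm <- do.call(rbind, lapply(
    split(res, list(res$arm, res$test_regime), drop = TRUE),
    function(d) data.frame(arm = d$arm[1], test_regime = d$test_regime[1],
                           mean_r = mean(d$accuracy_r),
                           se_r = mcse(d$accuracy_r),
                           mean_mse = mean(d$mse), se_mse = mcse(d$mse),
                           n = nrow(d), stringsAsFactors = FALSE)))
  rownames(by_arm) <- NULL
  paired <- do.call(rbind, lapply(split(res, res$test_regime), function(d) {
    u <- d[d$arm == "uncorrected", ]
    c_ <- d[d$arm == "pc_corrected", ]
    u <- u[order(u$replicate), ]; c_ <- c_[order(c_$replicate), ]
    dr <- u$accuracy_r - c_$accuracy_r
    dm <- u$mse - c_$mse
    n_pos <- sum(dr > 0)
    pval <- stats::binom.test(n_pos, length(dr),
                              alternative = "greater")$p.value
    data.frame(test_regime = d$test_regime[1],
               mean_dr = mean(dr), se_dr = mcse(dr),
               mean_dmse = mean(dm), se_dmse = mcse(dm),
               n_corrected_lower_r = n_pos, n = length(dr),
               sign_test_p = pval, stringsAsFactors = FALSE)
  }))
  rownames(paired) <- NULL
  list(by_arm = by_arm, paired = paired)
}
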