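#' REML ridge-regression marker BLUP
#'
#' Fits the mixed model `y = W b + X u + eps` with `u ~ N(0, sigma_u^2 I)`
#' and `eps ~ N(0, sigma_e^2 I)`, where `W` is an intercept plus optional
#' covariate columns (typically principal-component scores) and `X` is the
#' column-centered genotype matrix. All marker effects are shrunk jointly;
#' the shrinkage strength is not tuned but estimated by restricted maximum
#' likelihood.
#'
#' Computation follows the spectral approach: with `K = X X^T = Q T Q^T`,
#' rotating by `Q^T` diagonalizes the covariance of `y`, so the restricted
#' likelihood is a cheap one-dimensional function of the variance ratio
#' `delta = sigma_e^2 / sigma_u^2`, profiled over `b` and the scale. The
#' ratio is found by bounded search over `log(delta)` in `[-25, 25]` with
#' relative tolerance 1e-8. Given `delta`, the marker BLUP equals the
#' closed-form ridge solution `(X^T X + delta I)^{-1} X^T (y - W b)`.
#'
#' @param y Phenotype vector (finite values).
#' @param X Genotype matrix, N x L; centered internally (means kept for
#'   prediction).
#' @param covariates Optional numeric matrix of fixed-effect covariates
#'   (an intercept is always added).
#' @param decomposition Optional precomputed `eigen(tcrossprod(Xc),
#'   symmetric = TRUE)` of the centered genotype kernel, to share one
#'   decomposition across several fits on the same genotypes.
#' @param tol Relative tolerance of the REML line search.
#' @return A `marker_blup`: `fixed_effects` (intercept first),
#'   `marker_effects` (length L), `intercept_raw` (intercept on the raw,
#'   uncentered genotype scale), `var_marker` (sigma_u^2), `var_resid`
#'   (sigma_e^2), `delta`, `reml_loglik`, `fitted`, `snp_means`,
#'   `covariate_spec`.
#' @examples
#' p <- sim_params(n_individuals = 120, n_snps = 60, seed = 3)
#' co <- make_cohort(p)
#' fit <- fit_marker_blup(co$phenotype, co$genotypes)
#' fit$var_marker / fit$var_resid
#' @export
fit_marker_blup <- function(y, X, covariates = NULL, decomposition = NULL,
                            tol = 1e-8) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (any(!is.finite(y)))
    stop("phenotype contains non-finite values", call. = FALSE)
  stopifnot(nrow(X) == n)
  W <- if (is.null(covariates)) matrix(1, n, 1)
       else cbind(1, as.matrix(covariates))
  p <- ncol(W)
  if (n <= p + 1)
    stop("need n > number of covariate columns + 1", call. = FALSE)
  if (qr(W)$rank < p)
    stop("covariates are collinear with the intercept or each other",
         call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  ev <- if (is.null(decomposition)) eigen(tcrossprod(Xc), symmetric = TRUE)
        else decomposition
  theta <- pmax(ev$values, 0)
  Q <- ev$vectors
  ystar <- drop(crossprod(Q, y))
  Wstar <- crossprod(Q, W)

  # restricted log-likelihood of log(delta), profiled over b and sigma_u^2
  rll <- function(ldelta) {
    dvec <- theta + exp(ldelta)
    Wd <- Wstar / dvec
    A <- crossprod(Wstar, Wd)
    b <- solve(A, crossprod(Wd, ystar))
    r <- ystar - Wstar %*% b
    q <- sum(r^2 / dvec)
    if (q <= 0) return(1e10)  # exact fit; handled by the caller
    s2u <- q / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2u) + sum(log(dvec)) +
              determinant(A, logarithm = TRUE)$modulus + (n - p))
  }
  opt <- stats::optimize(function(l) -rll(l), interval = c(-25, 25),
                         tol = tol)
  if (!is.finite(opt$objective))
    stop("REML optimization failed to produce a finite restricted ",
         "likelihood (delta search diagnostics: objective = ",
         opt$objective, ")", call. = FALSE)
  delta <- exp(opt$minimum)
  dvec <- theta + delta
  Wd <- Wstar / dvec
  A <- crossprod(Wstar, Wd)
  b <- drop(solve(A, crossprod(Wd, ystar)))
  r <- ystar - drop(Wstar %*% b)
  q <- sum(r^2 / dvec)
  s2u <- q / (n - p)
  if (s2u < 1e-12) {
    # no marker variance: fall back to the fixed-effects-only fit
    ols <- stats::lm.fit(W, y)
    b <- ols$coefficients
    u <- numeric(ncol(X))
    s2u <- 0
    s2e <- sum(ols$residuals^2) / max(1, n - p)
    fitted <- drop(W %*% b)
  } else {
    s2e <- delta * s2u
    # BLUP: u = Xc' (K + delta I)^{-1} (y - W b)
    resid_rot <- r / dvec
    u <- drop(crossprod(Xc, Q %*% resid_rot))
    fitted <- drop(W %*% b) + drop(Xc %*% u)
  }
  structure(list(fixed_effects = b, marker_effects = u,
                 intercept_raw = b[1] - sum(mu * u),
                 var_marker = s2u, var_resid = s2e, delta = delta,
                 reml_loglik = -opt$objective,
                 fitted = fitted, snp_means = mu,
                 covariate_spec = if (is.null(covariates)) "intercept only"
                 else sprintf("intercept + %d covariate column(s)",
                              ncol(as.matrix(covariates)))),
            class = "marker_blup")
}

#' @export
print.marker_blup <- function(x, ...) {
  cat("REML ridge-regression marker BLUP\n")
  cat(sprintf("  %s; %d marker effects\n", x$covariate_spec,
              length(x$marker_effects)))
  cat(sprintf("  sigma_u^2 = %.4g, sigma_e^2 = %.4g (delta = %.4g), REML logLik = %.3f\n",
              x$var_marker, x$var_resid, x$delta, x$reml_loglik))
  invisible(x)
}

#' Predict phenotypes from a marker BLUP fit
#'
#' By default the prediction is the genetic score only: raw genotypes
#' times marker effects plus the raw-scale intercept (ancestry covariates
#' in the training fit absorb structure but do not travel with the
#' prediction). Set `include_covariates = TRUE` and supply `scores_new`
#' to add the covariate fixed-effect contribution.
#'
#' @param fit A `marker_blup`.
#' @param X_new Genotype matrix over the training SNP set.
#' @param scores_new Covariate matrix for the new individuals (required
#'   when `include_covariates = TRUE`).
#' @param include_covariates Add the fixed-effect covariate contribution?
#' @return Numeric prediction vector.
#' @export
predict_phenotype <- function(fit, X_new, scores_new = NULL,
                              include_covariates = FALSE) {
  stopifnot(inherits(fit, "marker_blup"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(fit$marker_effects))
    stop("X_new SNP set does not match the training fit", call. = FALSE)
  pred <- drop(X_new %*% fit$marker_effects) + fit$intercept_raw
  if (include_covariates) {
    if (is.null(scores_new))
      stop("include_covariates = TRUE requires `scores_new`", call. = FALSE)
    bc <- fit$fixed_effects[-1]
    if (length(bc) == 0)
      stop("fit has no covariate fixed effects to include", call. = FALSE)
    pred <- pred + drop(as.matrix(scores_new) %*% bc)
  }
  pred
}

#' Prediction accuracy metrics
#'
#' Pearson correlation (the headline accuracy), mean squared error, and
#' squared correlation between predicted and observed values. A constant
#' prediction has undefined correlation; it is reported as 0 with
#' `degenerate = TRUE`.
#'
#' @param predicted,observed Numeric vectors of equal length >= 3;
#'   `observed` must be non-constant.
#' @return List with `r`, `mse`, `r2`, `degenerate`.
#' @export
evaluate_accuracy <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 3)
  if (stats::sd(observed) == 0)
    stop("observed values are constant; accuracy is undefined",
         call. = FALSE)
  degenerate <- stats::sd(predicted) == 0
  r <- if (degenerate) 0 else stats::cor(predicted, observed)
  list(r = r, mse = mean((predicted - observed)^2), r2 = r^2,
       degenerate = degenerate)
}
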