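#' Principal components of a genotype matrix
#'
#' Columns are centered by their sample mean and scaled to unit sample
#' variance, monomorphic SNPs are dropped (with a warning), and the top
#' `k` principal components are extracted. For N <= L the eigendecomposition
#' of the individual-by-individual kernel is used, otherwise the SNP
#' covariance; the results are identical. Column signs are fixed so that
#' the largest-magnitude loading in each component is positive, making
#' results deterministic.
#'
#' @param X Genotype (or any numeric) matrix, individuals in rows.
#' @param k Number of components to keep (default 20).
#' @return A `pc_basis`: `loadings` (L_kept x k, orthonormal columns),
#'   `scores` (N x k, equal to standardized genotypes times loadings),
#'   `eigenvalues` (k, descending; variances with denominator N - 1),
#'   `snp_means`, `snp_scales` (per kept SNP), `kept_snps` (column indices
#'   into the original matrix), `n_snps_total`.
#' @export
compute_pcs <- function(X, k = 20) {
  X <- as.matrix(X)
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- which(sdv > 0)
  if (length(keep) == 0)
    stop("all SNPs are monomorphic; no principal components exist",
         call. = FALSE)
  if (length(keep) < ncol(X))
    warning(sprintf("%d monomorphic SNP(s) dropped before PCA",
                    ncol(X) - length(keep)))
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  rank_max <- min(n - 1L, length(keep))
  if (k > rank_max)
    stop(sprintf("k = %d exceeds the maximum rank %d of the standardized matrix",
                 k, rank_max), call. = FALSE)
  if (n <= length(keep)) {
    K <- tcrossprod(Z)
    ev <- eigen(K, symmetric = TRUE)
    d2 <- pmax(ev$values[seq_len(k)], 0)
    d <- sqrt(d2)
    U <- ev$vectors[, seq_len(k), drop = FALSE]
    scores <- sweep(U, 2, d, "*")
    loadings <- crossprod(Z, U)
    loadings <- sweep(loadings, 2, pmax(d, .Machine$double.eps), "/")
  } else {
    C <- crossprod(Z)
    ev <- eigen(C, symmetric = TRUE)
    d2 <- pmax(ev$values[seq_len(k)], 0)
    d <- sqrt(d2)
    loadings <- ev$vectors[, seq_len(k), drop = FALSE]
    scores <- Z %*% loadings
  }
  sgn <- apply(loadings, 2, function(v) {
    s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s
  })
  loadings <- sweep(loadings, 2, sgn, "*")
  scores <- sweep(scores, 2, sgn, "*")
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(loadings = loadings, scores = scores,
                 eigenvalues = d2 / (n - 1),
                 snp_means = mu[keep], snp_scales = sdv[keep],
                 kept_snps = keep, n_snps_total = ncol(X)),
            class = "pc_basis")
}

#' @export
print.pc_basis <- function(x, ...) {
  cat(sprintf("PC basis: %d components over %d SNPs (%d individuals)\n",
              ncol(x$loadings), length(x$kept_snps), nrow(x$scores)))
  cat("  leading eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Project new individuals into a trained PC basis
#'
#' New genotypes are standardized with the *training* means and scales
#' (SNPs monomorphic in training are ignored) and multiplied into the
#' training loadings, so out-of-sample individuals can be corrected in the
#' same coordinate system the model was trained in.
#'
#' @param basis A `pc_basis` from [compute_pcs()].
#' @param X_new Genotype matrix over the same SNP set as training.
#' @return Score matrix (nrow(X_new) x k).
#' @export
project_pcs <- function(basis, X_new) {
  stopifnot(inherits(basis, "pc_basis"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != basis$n_snps_total)
    stop(sprintf("X_new has %d SNPs but the basis was trained on %d",
                 ncol(X_new), basis$n_snps_total), call. = FALSE)
  Z <- sweep(sweep(X_new[, basis$kept_snps, drop = FALSE], 2,
                   basis$snp_means), 2, basis$snp_scales, "/")
  s <- Z %*% basis$loadings
  colnames(s) <- colnames(basis$loadings)
  s
}
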