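#' Is population structure detectable at this sample size?
#'
#' Structure of differentiation `fst` in a dataset of `n` individuals at
#' `L` SNPs sits above the spiked-covariance phase transition when
#' `D = fst * sqrt(n * L) > 1`; below it, the leading eigenvector carries
#' asymptotically no ancestry information, so the structure is present but
#' cannot be corrected for. `n_required = ceiling(1 / (fst^2 * L))` is the
#' sample size at which the transition is crossed.
#'
#' @param n Sample size.
#' @param L Number of SNPs.
#' @param fst Differentiation between the latent populations (>= 0).
#' @return List with `detectable` (logical), `statistic` (D), and
#'   `n_required` (`Inf` when `fst = 0`).
#' @examples
#' detectability(n = 2000, L = 4000, fst = 0.01)
#' @export
detectability <- function(n, L, fst) {
  stopifnot(n >= 1, L >= 1, fst >= 0)
  D <- fst * sqrt(n * L)
  list(detectable = D > 1,
       statistic = D,
       n_required = if (fst == 0) Inf else ceiling(1 / (fst^2 * L)))
}

#' Hudson-type FST between two groups
#'
#' Ratio-of-averages Hudson estimator on haploid 0/1 genotypes: per-SNP
#' numerators `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominators `p1(1-p2) + p2(1-p1)` are summed across SNPs before the
#' ratio is taken, and the result is clamped at 0. SNPs monomorphic in
#' both groups for the same allele are excluded.
#'
#' @param X Genotype matrix with entries in `{0, 1}`.
#' @param groups Vector with exactly two distinct values assigning rows to
#'   groups; each group must contain at least 2 individuals.
#' @return A single nonnegative FST estimate.
#' @export
empirical_fst <- function(X, groups) {
  X <- as.matrix(X)
  g <- as.factor(groups)
  if (nlevels(g) != 2)
    stop("`groups` must define exactly two groups", call. = FALSE)
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  if (n1 < 2 || n2 < 2)
    stop("each group must contain at least 2 individuals", call. = FALSE)
  p1 <- colMeans(X[g == levels(g)[1], , drop = FALSE])
  p2 <- colMeans(X[g == levels(g)[2], , drop = FALSE])
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  if (!any(keep))
    stop("all SNPs are monomorphic in both groups", call. = FALSE)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  max(0, sum(num[keep]) / sum(den[keep]))
}

#' Number of principal components above the detection threshold
#'
#' Counts leading eigenvalues of the standardized genotype kernel, scaled
#' by 1/L, that exceed the Marchenko-Pastur bulk edge `(1 + sqrt(n/L))^2`.
#' Eigenvalues below the edge are indistinguishable from sampling noise,
#' so the count is the number of ancestry axes the sample can actually
#' see — smaller samples see fewer.
#'
#' @param X Genotype matrix.
#' @param k_max Cap on the number of components considered.
#' @return Integer count of detectable components.
#' @export
n_detectable_pcs <- function(X, k_max = 20) {
  X <- as.matrix(X)
  n <- nrow(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- sdv > 0
  L <- sum(keep)
  if (L == 0) return(0L)
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, colMeans(X)[keep]), 2,
             sdv[keep], "/")
  k_max <- min(k_max, n - 1L, L)
  lam <- eigen(tcrossprod(Z), symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[seq_len(k_max)] / L
  edge <- (1 + sqrt(n / L))^2
  sum(lam > edge)
}

#' Fit an SVD basis to a reference sharing matrix
#'
#' Columns of the reference individuals-by-populations sharing matrix are
#' centered and standardized to unit variance, then decomposed by SVD.
#' Zero-variance columns are dropped with a warning. Axis signs follow the
#' same convention as [compute_pcs()].
#'
#' @param ref A `sharing_matrix` (or plain numeric matrix) of reference
#'   individuals.
#' @return A `reference_basis`: `center`, `scale` (per kept column),
#'   `right_vectors` (K_kept x r, orthonormal), `singular_values`
#'   (descending), `labels`, `kept_cols`, and `ref_scores` (the reference
#'   individuals' own coordinates, left singular vectors times singular
#'   values).
#' @export
fit_reference_basis <- function(ref) {
  vals <- if (inherits(ref, "sharing_matrix")) ref$values else as.matrix(ref)
  labels <- if (inherits(ref, "sharing_matrix")) ref$labels
            else colnames(vals) %||% paste0("ref", seq_len(ncol(vals)))
  mu <- colMeans(vals)
  sdv <- apply(vals, 2, stats::sd)
  keep <- which(sdv > 0)
  if (length(keep) < ncol(vals))
    warning(sprintf("%d zero-variance reference column(s) dropped",
                    ncol(vals) - length(keep)))
  if (length(keep) < 2)
    stop("fewer than 2 usable reference columns", call. = FALSE)
  Z <- sweep(sweep(vals[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep],
             "/")
  sv <- svd(Z)
  sgn <- apply(sv$v, 2, function(v) {
    s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s
  })
  V <- sweep(sv$v, 2, sgn, "*")
  U <- sweep(sv$u, 2, sgn, "*")
  structure(list(center = mu[keep], scale = sdv[keep],
                 right_vectors = V, singular_values = sv$d,
                 labels = labels[keep], kept_cols = keep,
                 n_cols_total = ncol(vals),
                 ref_scores = sweep(U, 2, sv$d, "*")),
            class = "reference_basis")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Project a cohort into a reference SVD basis
#'
#' Cohort sharing rows are standardized by the *reference* center and
#' scale, then multiplied into the reference right singular vectors. A
#' cohort row identical to a reference row maps to that reference
#' individual's coordinates; a row equal to the reference column means
#' maps to the origin.
#'
#' @param basis A `reference_basis` from [fit_reference_basis()].
#' @param cohort_sharing A `sharing_matrix` (or matrix) with the same K
#'   columns in the same label order as the reference.
#' @return Score matrix (n x r).
#' @export
project_cohort <- function(basis, cohort_sharing) {
  stopifnot(inherits(basis, "reference_basis"))
  vals <- if (inherits(cohort_sharing, "sharing_matrix"))
    cohort_sharing$values else as.matrix(cohort_sharing)
  labs <- if (inherits(cohort_sharing, "sharing_matrix"))
    cohort_sharing$labels else colnames(vals)
  if (ncol(vals) != basis$n_cols_total)
    stop(sprintf("cohort sharing matrix has %d columns; the reference basis labels %d",
                 ncol(vals), basis$n_cols_total), call. = FALSE)
  if (!is.null(labs) &&
      !identical(unname(labs[basis$kept_cols]), unname(basis$labels)))
    stop("cohort sharing-matrix labels do not match the reference basis",
         call. = FALSE)
  Z <- sweep(sweep(vals[, basis$kept_cols, drop = FALSE], 2, basis$center),
             2, basis$scale, "/")
  s <- Z %*% basis$right_vectors
  colnames(s) <- paste0("PC", seq_len(ncol(s)))
  s
}

#' Variance in a phenotype explained by ancestry scores
#'
#' Ordinary least squares of the phenotype on all score columns plus an
#' intercept; returns the multiple R-squared and, for interpretation, each
#' component's marginal (single-regressor) R-squared. Collinear columns
#' are dropped before the joint fit.
#'
#' @param scores Numeric matrix of ancestry scores (n x k).
#' @param phenotype Numeric response of length n.
#' @return List with `r2` (multiple R-squared), `per_component` (named
#'   marginal R-squared vector), and `n_used`.
#' @export
variance_explained <- function(scores, phenotype) {
  scores <- as.matrix(scores)
  n <- length(phenotype)
  stopifnot(nrow(scores) == n)
  if (n < ncol(scores) + 2)
    stop("need more observations than score columns + 1", call. = FALSE)
  qrX <- qr(cbind(1, scores))
  drop_cols <- integer(0)
  if (qrX$rank < ncol(scores) + 1) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    keep <- setdiff(keep, 1L) - 1L   # column indices into `scores`
    drop_cols <- setdiff(seq_len(ncol(scores)), keep)
    scores <- scores[, keep, drop = FALSE]
  }
  fit <- stats::lm.fit(cbind(1, scores), phenotype)
  tss <- sum((phenotype - mean(phenotype))^2)
  r2 <- 1 - sum(fit$residuals^2) / tss
  per <- apply(scores, 2, function(s) {
    f <- stats::lm.fit(cbind(1, s), phenotype)
    1 - sum(f$residuals^2) / tss
  })
  list(r2 = r2, per_component = per, n_used = n, dropped = drop_cols)
}

#' Radius-restricted Gaussian smoothing on two ancestry axes
#'
#' Evaluates a Gaussian-kernel weighted mean of `values` at every node of
#' a regular grid over two score axes. Nodes farther than `max_dist` from
#' every observation are masked (`NA`): the surface is only drawn where
#' there is local data, with the default radius 0.03.
#'
#' @param points n x 2 matrix of coordinates (two score axes).
#' @param values Numeric vector of length n to smooth.
#' @param grid Either a single integer (nodes per axis, default 50) or a
#'   list of two numeric vectors giving the node positions.
#' @param bandwidth Gaussian kernel standard deviation (> 0).
#' @param max_dist Masking radius (default 0.03).
#' @return A `smooth_grid`: `x`, `y` node vectors, `z` value matrix
#'   (length(x) x length(y), `NA` where masked), `mask` logical matrix
#'   (TRUE = masked).
#' @export
kernel_smooth_2d <- function(points, values, grid = 50, bandwidth,
                             max_dist = 0.03) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) == length(values),
            nrow(points) >= 1)
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be a positive real", call. = FALSE)
  if (max_dist <= 0) stop("max_dist must be positive", call. = FALSE)
  if (is.list(grid)) {
    gx <- grid[[1]]; gy <- grid[[2]]
  } else {
    gx <- seq(min(points[, 1]), max(points[, 1]), length.out = grid)
    gy <- seq(min(points[, 2]), max(points[, 2]), length.out = grid)
    if (min(points[, 1]) == max(points[, 1])) gx <- points[1, 1]
    if (min(points[, 2]) == max(points[, 2])) gy <- points[1, 2]
  }
  nodes <- cbind(rep(gx, times = length(gy)),
                 rep(gy, each = length(gx)))
  d2 <- outer(nodes[, 1], points[, 1], "-")^2 +
    outer(nodes[, 2], points[, 2], "-")^2
  w <- exp(-d2 / (2 * bandwidth^2))
  z <- as.vector(w %*% values) / rowSums(w)
  mask <- sqrt(apply(d2, 1, min)) > max_dist
  z[mask] <- NA_real_
  structure(list(x = gx, y = gy,
                 z = matrix(z, length(gx), length(gy)),
                 mask = matrix(mask, length(gx), length(gy)),
                 bandwidth = bandwidth, max_dist = max_dist),
            class = "smooth_grid")
}
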