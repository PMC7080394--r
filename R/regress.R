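# Two-way within (double-demeaning) regression machinery shared by the DiD
# and interactive fixed effects estimators. All regressions operate on n x T
# matrices vectorised column-major, so observation (i, t) sits at row
# (t - 1) * n + i and the cluster id of an observation is its unit index.

# Double-demean an n x T matrix: subtract row and column means, add back the
# grand mean. For a balanced panel this is the exact projection removing
# additive unit and period effects.
demean2 <- function(M) {
  M - rowMeans(M) - rep(colMeans(M), each = nrow(M)) + mean(M)
}

# Build the within design from a list of n x T regressor matrices, dropping
# columns with (numerically) zero variance after demeaning and columns that
# are collinear with earlier ones. Returns the design, the kept index, and
# the QR factorisation reused for repeated solves.
within_design <- function(xmats, warn_drop = TRUE) {
  p <- length(xmats)
  if (p == 0L)
    return(list(A = NULL, keep = integer(0), qr = NULL))
  A <- vapply(xmats, function(M) as.vector(demean2(M)),
              numeric(length(xmats[[1]])))
  A <- matrix(A, ncol = p)
  scale <- sqrt(colMeans(A^2))
  nz <- scale > 1e-10 * max(scale, 1)
  qrA <- qr(A[, nz, drop = FALSE])
  keep_nz <- sort(qrA$pivot[seq_len(qrA$rank)])
  keep <- which(nz)[keep_nz]
  if (warn_drop && length(keep) < p)
    warning("dropping ", p - length(keep),
            " collinear regressor(s) after the within transformation")
  A <- A[, keep, drop = FALSE]
  list(A = A, keep = keep, qr = qr(A))
}

# Solve the within regression of response matrix Y (n x T) on a prepared
# design; returns coefficients (in kept-column order) and the residual
# matrix of the *within* regression.
within_solve <- function(design, Y) {
  y <- as.vector(demean2(Y))
  if (is.null(design$A))
    return(list(coef = numeric(0), resid = matrix(y, nrow(Y), ncol(Y))))
  coef <- qr.coef(design$qr, y)
  resid <- y - design$A %*% coef
  list(coef = as.numeric(coef),
       resid = matrix(resid, nrow(Y), ncol(Y)))
}

# CR1 cluster-robust covariance of within-regression coefficients with
# clusters = units. K counts *all* estimated parameters of the equivalent
# dummy-variable regression (fixed effects included), so the finite-sample
# factor is G/(G-1) * (N-1)/(N-K) and the result matches the sandwich/HC1
# cluster covariance of the LSDV fit.
cluster_vcov_within <- function(design, resid_mat, n_fe_params) {
  n <- nrow(resid_mat); T_ <- ncol(resid_mat)
  G <- n; N <- n * T_
  p <- ncol(design$A)
  K <- p + n_fe_params
  if (G < 2) stop("cluster-robust variance requires at least 2 clusters (units)")
  u <- as.vector(resid_mat)
  Xu <- design$A * u
  cl <- rep(seq_len(n), times = T_)
  S <- rowsum(Xu, cl)                        # G x p cluster score sums
  meat <- crossprod(S)
  bread <- chol2inv(qr.R(design$qr))         # (A'A)^{-1}
  adj <- G / (G - 1) * (N - 1) / (N - K)
  V <- adj * bread %*% meat %*% bread
  (V + t(V)) / 2
}

# Recover additive effects under the sum-to-zero normalisation from the
# residual-after-covariates matrix: intercept = grand mean, unit and period
# effects centred. Exact OLS for a balanced panel.
additive_effects <- function(Rmat) {
  mu <- mean(Rmat)
  list(intercept = mu,
       unit_effects = rowMeans(Rmat) - mu,
       time_effects = colMeans(Rmat) - mu)
}

# Expand covariate array into a list of n x T matrices.
covariate_list <- function(covariates) {
  k <- dim(covariates)[3]
  lapply(seq_len(k), function(j) covariates[, , j])
}
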