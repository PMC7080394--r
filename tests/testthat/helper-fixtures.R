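# Small panels and factor data built in code for the tests.

# Deterministic toy panel: n units, T periods, optional covariate effect.
toy_panel <- function(n = 6, T_ = 8, last_pre = 5, n_treated = 2,
                      effect = 2, noise = 0.1, k = 1, seed = 1) {
  set.seed(seed)
  treated <- c(rep(1, n_treated), rep(0, n - n_treated))
  Y <- outer(rnorm(n), rep(1, T_)) + rep(runif(T_, 0, 2), each = n) +
    noise * matrix(rnorm(n * T_), n, T_)
  covs <- NULL
  if (k > 0) {
    covs <- array(rnorm(n * T_ * k), dim = c(n, T_, k))
    for (j in seq_len(k)) Y <- Y + 0.5 * covs[, , j]
  }
  D <- outer(treated, as.numeric(seq_len(T_) > last_pre))
  Y <- Y + effect * D
  panel_dataset(Y, treated, last_pre, covariates = covs)
}

# Noise-free rank-R factor panel with an additive post effect `delta` on
# treated units; returns the panel and its building blocks.
factor_panel <- function(n = 30, T_ = 12, R = 2, n_treated = 5,
                         last_pre = 8, delta = 3, noise = 0, seed = 2) {
  set.seed(seed)
  mu <- matrix(rnorm(n * R), n, R)
  lam <- matrix(rnorm(T_ * R), T_, R)
  treated <- c(rep(1, n_treated), rep(0, n - n_treated))
  Y <- mu %*% t(lam) + noise * matrix(rnorm(n * T_), n, T_)
  D <- outer(treated, as.numeric(seq_len(T_) > last_pre))
  list(panel = panel_dataset(Y + delta * D, treated, last_pre),
       mu = mu, lam = lam, delta = delta, treated = treated)
}

# Brute-force grid search over the unit simplex for <= 3 donors.
grid_search_weights <- function(x1, X0, v = NULL, step = 0.002) {
  J <- ncol(X0)
  if (is.null(v)) v <- rep(1 / length(x1), length(x1))
  v <- v / sum(v)
  obj <- function(w) sum(v * (x1 - as.numeric(X0 %*% w))^2)
  best <- NULL; best_val <- Inf
  g <- seq(0, 1, by = step)
  if (J == 2) {
    for (w1 in g) {
      val <- obj(c(w1, 1 - w1))
      if (val < best_val) { best_val <- val; best <- c(w1, 1 - w1) }
    }
  } else if (J == 3) {
    for (w1 in g) for (w2 in seq(0, 1 - w1, by = step)) {
      w <- c(w1, w2, 1 - w1 - w2)
      val <- obj(w)
      if (val < best_val) { best_val <- val; best <- w }
    }
  } else stop("grid oracle supports 2 or 3 donors")
  list(weights = best, objective = best_val)
}
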