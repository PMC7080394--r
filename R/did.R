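#' Two-way fixed-effects difference-in-differences
#'
#' Estimates the ATT as the coefficient on the treatment exposure indicator
#' \eqn{D_{it}} in the two-way fixed-effects regression
#' \deqn{Y_{it} = X_{it}'\beta + \mu_i + \lambda_t + D_{it}\tau + \varepsilon_{it},}
#' computed by the within (double-demeaning) transformation, which is
#' numerically identical to the least-squares dummy-variable fit. Inference
#' is cluster-robust (CR1) with clusters = units and a t reference
#' distribution on `G - 1` degrees of freedom.
#'
#' Under parallel trends the coefficient \eqn{\tau} identifies the ATT; with
#' heterogeneous unit effects it estimates the treated-sample average effect
#' in this balanced block-adoption design. Covariates that are collinear
#' with the fixed effects (e.g. time-invariant columns) are dropped with a
#' warning.
#'
#' @param panel a [panel_dataset()].
#' @param level confidence level for the reported interval.
#' @return an [att_result()] with `method = "did"`; `diagnostics` carries the
#'   full `did_fit` (coefficients, normalized fixed effects, CR1 vcov).
#' @export
fit_did <- function(panel, level = 0.95) {
  validate_panel(panel)
  fit <- did_fit(panel)
  n <- n_units(panel)
  post <- post_periods(panel)
  att <- fit$tau
  se <- sqrt(fit$vcov[1, 1])
  if (n >= 2 && is.finite(se)) {
    tstat <- att / se
    df <- fit$n_clusters - 1
    p <- 2 * stats::pt(-abs(tstat), df)
    q <- stats::qt(1 - (1 - level) / 2, df)
    ci <- att + c(-1, 1) * q * se
  } else {
    p <- NA_real_; ci <- c(NA_real_, NA_real_)
  }
  att_result("did", att, att_by_period = rep(att, length(post)),
             se = se, ci_low = ci[1], ci_high = ci[2], p_value = p,
             inference_method = "cluster_robust",
             diagnostics = list(fit = fit, last_pre = panel$last_pre))
}

# Core within estimation; returns the did_fit structure.
did_fit <- function(panel) {
  n <- n_units(panel); T_ <- n_periods(panel)
  k <- dim(panel$covariates)[3]
  xmats <- c(list(panel$exposure), covariate_list(panel$covariates))
  design <- within_design(xmats)
  if (!(1L %in% design$keep))
    stop("treatment indicator is collinear with the fixed effects; ATT not identified")
  sol <- within_solve(design, panel$outcome)
  coef <- sol$coef
  names(coef) <- c("tau", paste0("beta", seq_len(k)))[design$keep]
  tau <- coef[["tau"]]
  beta <- rep(0, k)
  kept_cov <- design$keep[design$keep > 1L] - 1L
  beta[kept_cov] <- coef[-1]
  dropped <- setdiff(seq_len(k), kept_cov)
  beta[dropped] <- NA_real_

  fitted_x <- matrix(0, n, T_)
  for (j in kept_cov) fitted_x <- fitted_x + beta[j] * panel$covariates[, , j]
  eff <- additive_effects(panel$outcome - fitted_x - tau * panel$exposure)
  n_fe <- 1L + (n - 1L) + (T_ - 1L)   # intercept + unit + period dummies
  vcov <- cluster_vcov_within(design, sol$resid, n_fe)
  dimnames(vcov) <- list(names(coef), names(coef))
  structure(
    list(tau = tau, beta = beta,
         intercept = eff$intercept,
         unit_effects = eff$unit_effects, time_effects = eff$time_effects,
         vcov = vcov, n_clusters = n, dropped_covariates = dropped,
         residuals = sol$resid),
    class = "did_fit")
}

#' CR1 cluster-robust covariance of a DiD fit
#'
#' Sandwich variance with unit-level score sums and the finite-sample
#' correction \eqn{G/(G-1)\cdot(N-1)/(N-K)}, where `G` is the number of
#' clusters (units), `N` the number of observations and `K` the number of
#' estimated coefficients including the fixed effects. Matches the
#' HC1-type clustered covariance of the equivalent dummy-variable
#' regression.
#'
#' @param fit a `did_fit` as stored in `fit_did()` diagnostics.
#' @param panel the `panel_dataset` the fit came from.
#' @return symmetric positive semidefinite matrix over `(tau, beta)`.
#' @export
cluster_robust_vcov <- function(fit, panel) {
  stopifnot(inherits(fit, "did_fit"))
  validate_panel(panel)
  if (n_units(panel) < 2)
    stop("cluster-robust variance requires at least 2 clusters (units)")
  k <- dim(panel$covariates)[3]
  xmats <- c(list(panel$exposure), covariate_list(panel$covariates))
  design <- within_design(xmats, warn_drop = FALSE)
  n_fe <- 1L + (n_units(panel) - 1L) + (n_periods(panel) - 1L)
  cluster_vcov_within(design, fit$residuals, n_fe)
}

#' Joint pre-trends test for the parallel trends assumption
#'
#' Augments the two-way fixed-effects regression, restricted to pre-treatment
#' periods, with treated-group x period interaction indicators (the first pre
#' period is the reference) and tests the joint null that all interaction
#' coefficients are zero with a cluster-robust Wald statistic, referred to an
#' F distribution with `(q, G - 1)` degrees of freedom.
#'
#' @param panel a [panel_dataset()] with at least 3 pre-treatment periods.
#' @return a list with `p_value`, `statistic` (the F form), `df` (numerator),
#'   and `df2`.
#' @export
parallel_trends_test <- function(panel) {
  validate_panel(panel)
  tp <- panel$last_pre
  if (tp < 3L) stop("parallel trends test requires at least 3 pre-treatment periods")
  pre <- seq_len(tp)
  n <- n_units(panel)
  Y <- panel$outcome[, pre, drop = FALSE]
  k <- dim(panel$covariates)[3]
  xm <- lapply(covariate_list(panel$covariates), function(M) M[, pre, drop = FALSE])
  inter <- lapply(2:tp, function(s) {
    M <- matrix(0, n, tp); M[, s] <- panel$treated; M
  })
  design <- within_design(c(inter, xm), warn_drop = FALSE)
  q_idx <- which(design$keep <= (tp - 1L))     # interaction coefficients kept
  if (!length(q_idx)) stop("no identifiable group x period interactions")
  sol <- within_solve(design, Y)
  n_fe <- 1L + (n - 1L) + (tp - 1L)
  V <- cluster_vcov_within(design, sol$resid, n_fe)
  theta <- sol$coef[q_idx]
  Vq <- V[q_idx, q_idx, drop = FALSE]
  W <- drop(crossprod(theta, solve(Vq, theta)))
  q <- length(q_idx)
  Fstat <- W / q
  p <- stats::pf(Fstat, q, n - 1, lower.tail = FALSE)
  list(p_value = p, statistic = Fstat, df = q, df2 = n - 1)
}
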