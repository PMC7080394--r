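#' Fit the factor model on control units only
#'
#' First stage of the generalized synthetic control method: the interactive
#' fixed effects model is estimated on the control units over the *entire*
#' sample period (no treatment term), yielding \eqn{\hat\beta} and the full
#' path of estimated factors \eqn{\hat\lambda_t}, including post-treatment
#' periods.
#'
#' @param panel a [panel_dataset()].
#' @param R number of interactive factors, or `"cv"` for cross-validated
#'   selection via [choose_factors_cv()].
#' @param R_max cap for cross-validation.
#' @param ... passed to [fit_ife()].
#' @return a `factor_model_fit` on the control sub-panel, with attribute
#'   `"cv"` holding the `cv_result` when selection was used.
#' @export
fit_controls <- function(panel, R = "cv", R_max = 5L, ...) {
  validate_panel(panel)
  cv <- NULL
  if (identical(R, "cv")) {
    cv <- choose_factors_cv(panel, R_max = R_max)
    R <- cv$chosen_R
  }
  ctrl <- split_groups(panel)$control
  fit <- fit_ife(ctrl$outcome, ctrl$covariates, R = R, ...)
  attr(fit, "cv") <- cv
  fit
}

#' Project factor loadings for treated units from pre-treatment fit
#'
#' For each treated unit, finds the loading vector \eqn{\hat\mu_i} (and a
#' unit-level intercept absorbing the additive unit effect) minimizing the
#' pre-treatment discrepancy between the observed outcome and the prediction
#' from the control-group fit: least squares of
#' \eqn{y_{i,pre} - X_{i,pre}\hat\beta - \hat\xi_{pre} - \hat c} on the
#' pre-period factor block.
#'
#' @param treated_pre_outcomes `m x t'` matrix of treated outcomes over the
#'   pre periods (or an `m x T` matrix together with `pre_idx`).
#' @param treated_pre_covariates `m x t' x k` (or `m x T x k`) covariate
#'   array aligned with the outcomes.
#' @param control_fit a `factor_model_fit` from [fit_controls()].
#' @param pre_idx indices of the pre periods within the columns supplied
#'   (default: all supplied columns, assumed to be the pre periods in order).
#' @return list with `loadings` (`m x R`) and `unit_intercepts` (length `m`).
#' @export
project_loadings <- function(treated_pre_outcomes, treated_pre_covariates,
                             control_fit, pre_idx = NULL) {
  Y <- as.matrix(treated_pre_outcomes)
  if (is.null(pre_idx)) pre_idx <- seq_len(ncol(Y))
  R <- control_fit$R
  if (length(pre_idx) < R + 1L)
    stop("loading projection is underdetermined: needs at least R + 1 = ",
         R + 1L, " pre-treatment periods, got ", length(pre_idx))
  project_loadings_idx(Y, treated_pre_covariates, control_fit, pre_idx)
}

# Internal workhorse: Y is m x T_sup (columns aligned with the control
# fit's periods), idx the periods to project on.
project_loadings_idx <- function(Y, covariates, control_fit, idx) {
  m <- nrow(Y)
  R <- control_fit$R
  if (is.null(covariates)) covariates <- array(numeric(0), dim = c(m, ncol(Y), 0))
  k <- dim(covariates)[3]
  Z <- Y[, idx, drop = FALSE]
  for (j in seq_len(k)) {
    b <- control_fit$beta[j]
    if (is.finite(b))
      Z <- Z - b * matrix(covariates[, idx, j], m, length(idx))
  }
  Z <- Z - rep(control_fit$intercept + control_fit$time_effects[idx],
               each = m)
  X <- cbind(1, control_fit$factors[idx, , drop = FALSE])  # t x (1 + R)
  cf <- qr.coef(qr(X), t(Z))                               # (1 + R) x m
  cf[is.na(cf)] <- 0
  list(unit_intercepts = as.numeric(cf[1, ]),
       loadings = matrix(t(cf)[, -1, drop = FALSE], m, R))
}

# Predict treated outcomes at periods `idx` from a control fit and a
# projection (treatment-free potential outcome).
predict_factor_outcome <- function(covariates, control_fit, projection, idx) {
  m <- length(projection$unit_intercepts)
  k <- if (is.null(covariates)) 0L else dim(covariates)[3]
  pred <- matrix(0, m, length(idx))
  for (j in seq_len(k)) {
    b <- control_fit$beta[j]
    if (is.finite(b))
      pred <- pred + b * matrix(covariates[, idx, j], m, length(idx))
  }
  pred <- pred + rep(control_fit$intercept + control_fit$time_effects[idx],
                     each = m)
  pred <- pred + projection$unit_intercepts
  if (control_fit$R > 0L)
    pred <- pred + projection$loadings %*%
      t(control_fit$factors[idx, , drop = FALSE])
  if (length(idx) == 1L) as.numeric(pred) else pred
}

#' ATT by the generalized synthetic control method
#'
#' Pipeline: (1) fit the interactive fixed effects model on control units
#' over all periods ([fit_controls()]); (2) project each treated unit's
#' factor loadings from its pre-treatment outcomes ([project_loadings()]);
#' (3) form the treatment-free counterfactual
#' \eqn{\hat Y^0_{it} = X_{it}\hat\beta + \hat\xi_t + \hat c_i +
#' \hat\lambda_t'\hat\mu_i} for every period; (4) effects
#' \eqn{\hat\tau_{it} = Y_{it} - \hat Y^0_{it}} on post periods, ATT = their
#' mean. Because loadings are estimated per treated unit without using
#' treated post-period data, the estimator is robust to heterogeneous
#' treatment effects. Inference is by parametric bootstrap.
#'
#' @param panel a [panel_dataset()].
#' @param R factor count or `"cv"`.
#' @param R_max cap for cross-validation.
#' @param inference `"bootstrap"` or `"none"`.
#' @param B number of bootstrap replications (default 500).
#' @param seed integer seed for the bootstrap (required when
#'   `inference = "bootstrap"`).
#' @return an [att_result()] with `method = "gsc"`; diagnostics include the
#'   chosen `R`, per-unit per-period effects, the counterfactual matrix, the
#'   mean pre-period gap (a specification diagnostic that should be near 0),
#'   and the `gsc_fit` object.
#' @export
estimate_gsc_att <- function(panel, R = "cv", R_max = 5L,
                             inference = c("bootstrap", "none"),
                             B = 500L, seed = NULL) {
  inference <- match.arg(inference)
  validate_panel(panel)
  fit <- gsc_fit(panel, R = R, R_max = R_max)
  post <- post_periods(panel)
  boot <- NULL
  se <- ci_low <- ci_high <- p <- NA_real_
  if (inference == "bootstrap") {
    if (is.null(seed)) stop("a seed is required for bootstrap inference")
    boot <- parametric_bootstrap(panel, fit, B = B, seed = seed)
    se <- boot$se; ci_low <- boot$ci_low; ci_high <- boot$ci_high
    p <- boot$p_value
  }
  att_result("gsc", fit$att,
             att_by_period = colMeans(fit$effects),
             se = se, ci_low = ci_low, ci_high = ci_high, p_value = p,
             inference_method = if (inference == "bootstrap") "bootstrap" else "none",
             diagnostics = list(R = fit$control_fit$R,
                                cv = attr(fit$control_fit, "cv"),
                                fit = fit,
                                pre_mean_gap = fit$pre_mean_gap,
                                last_pre = panel$last_pre,
                                bootstrap = boot))
}

#' Full GSC fit object
#'
#' Runs stages (1)-(3) of [estimate_gsc_att()] and returns the intermediate
#' quantities: the control-group factor fit, projected treated loadings, the
#' counterfactual outcome matrix over all periods, per-unit post-period
#' effects, and the ATT.
#'
#' @inheritParams estimate_gsc_att
#' @return object of class `gsc_fit`.
#' @export
gsc_fit <- function(panel, R = "cv", R_max = 5L) {
  validate_panel(panel)
  cfit <- fit_controls(panel, R = R, R_max = R_max)
  trt <- split_groups(panel)$treated
  tp <- panel$last_pre
  if (tp < cfit$R + 1L)
    stop("GSC requires at least R + 1 = ", cfit$R + 1L,
         " pre-treatment periods")
  proj <- project_loadings_idx(trt$outcome, trt$covariates, cfit,
                               seq_len(tp))
  allT <- seq_len(n_periods(panel))
  Y0 <- predict_factor_outcome(trt$covariates, cfit, proj, allT)
  Y0 <- matrix(Y0, nrow(trt$outcome), length(allT))
  post <- post_periods(panel)
  effects <- trt$outcome[, post, drop = FALSE] - Y0[, post, drop = FALSE]
  pre_gap <- trt$outcome[, seq_len(tp), drop = FALSE] -
    Y0[, seq_len(tp), drop = FALSE]
  structure(
    list(control_fit = cfit,
         treated_loadings = proj$loadings,
         treated_intercepts = proj$unit_intercepts,
         counterfactual = Y0,
         effects = effects,
         att = mean(effects),
         pre_mean_gap = mean(pre_gap),
         last_pre = tp),
    class = "gsc_fit")
}

#' @export
print.gsc_fit <- function(x, ...) {
  cat("Generalized synthetic control fit (R = ", x$control_fit$R, ")\n",
      sep = "")
  cat("  ATT over post periods: ", format(x$att, digits = 5), "\n", sep = "")
  cat("  mean pre-period gap (should be ~0): ",
      format(x$pre_mean_gap, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Parametric bootstrap for the GSC estimator
#'
#' Builds `B` resampled datasets from the fitted model: each unit's
#' model-implied outcome path (treatment-free for treated units, with the
#' estimated effects re-added in post periods) plus a full residual *series*
#' drawn with replacement from the control-group residual pool. Resampling
#' whole unit series preserves within-unit serial dependence. The complete
#' GSC pipeline is re-run on each resampled dataset with the factor count
#' fixed at the original fit's `R`.
#'
#' @param panel the original [panel_dataset()].
#' @param fit a [gsc_fit()].
#' @param B number of replications (>= 2).
#' @param seed integer seed (required; the draws are reproducible).
#' @return object of class `bootstrap_result`: `draws`, `se` (their standard
#'   deviation), normal-approximation `ci_low`/`ci_high` at 95%, two-sided
#'   normal `p_value`, `B`, `seed`. A percentile interval is also reported
#'   as `ci_percentile`.
#' @export
parametric_bootstrap <- function(panel, fit, B = 500L, seed) {
  stopifnot(inherits(fit, "gsc_fit"))
  if (missing(seed) || is.null(seed)) stop("seed is required for the bootstrap")
  B <- as.integer(B)
  if (B < 2L) stop("B must be at least 2")
  validate_panel(panel)
  tr <- panel$treated == 1
  n <- n_units(panel); T_ <- n_periods(panel)
  post <- post_periods(panel)
  cfit <- fit$control_fit
  Rfix <- cfit$R
  n_ctrl <- sum(!tr); n_trt <- sum(tr)

  implied <- matrix(NA_real_, n, T_)
  implied[!tr, ] <- cfit$fitted
  Y0t <- fit$counterfactual
  Y0t[, post] <- Y0t[, post] + fit$effects
  implied[tr, ] <- Y0t
  # residuals of the control fit are deflated by estimation; rescale to the
  # unbiased error scale before resampling
  N0 <- n_ctrl * T_
  df0 <- min(length(cfit$design$keep) + n_ctrl + T_ - 1 +
               Rfix * (n_ctrl + T_ - Rfix), N0 - 1)
  pool <- cfit$residuals * sqrt(N0 / (N0 - df0))

  draws <- numeric(B)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  for (b in seq_len(B)) {
    idx <- sample.int(n_ctrl, n, replace = TRUE)
    Yb <- implied + pool[idx, , drop = FALSE]
    pb <- panel_dataset(Yb, panel$treated, panel$last_pre,
                        covariates = if (dim(panel$covariates)[3])
                          panel$covariates else NULL,
                        unit_ids = panel$unit_ids, time_ids = panel$time_ids)
    draws[b] <- gsc_fit(pb, R = Rfix)$att
  }
  se <- stats::sd(draws)
  att <- fit$att
  structure(
    list(draws = draws, se = se,
         ci_low = att - 1.96 * se, ci_high = att + 1.96 * se,
         ci_percentile = unname(stats::quantile(draws, c(0.025, 0.975))),
         p_value = 2 * stats::pnorm(-abs(att / se)),
         B = B, seed = as.integer(seed)),
    class = "bootstrap_result")
}
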