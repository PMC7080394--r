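#' Interactive fixed effects by iterative principal components
#'
#' Fits the factor-augmented panel regression
#' \deqn{Y_{it} = X_{it}'\beta + \alpha_i + \xi_t + \lambda_t'\mu_i
#'   + D_{it}\tau + \varepsilon_{it}}
#' with `R` interactive factors on top of additive two-way effects, by
#' alternating least squares: (a) given the current common component
#' \eqn{\lambda_t'\mu_i}, estimate \eqn{(\beta, \tau)} and the additive
#' effects by the two-way within regression; (b) given
#' \eqn{(\beta, \tau, \alpha, \xi)}, extract the rank-`R` principal
#' components (truncated SVD) of the residual matrix. Each half-step is an
#' exact minimizer, so the sum of squared residuals is non-increasing.
#'
#' Factors are normalized so that \eqn{\Lambda'\Lambda / T = I_R} and the
#' loading cross-product is diagonal; only the product \eqn{\lambda_t'\mu_i}
#' is identified and used downstream.
#'
#' @param outcome numeric `n x T` outcome matrix.
#' @param covariates optional `n x T x k` covariate array (or a list of
#'   `n x T` matrices).
#' @param R number of interactive factors, `0 <= R <= min(n, T) - 1`.
#' @param exposure optional `n x T` binary treatment exposure matrix; when
#'   supplied a homogeneous treatment coefficient \eqn{\tau} is estimated
#'   jointly.
#' @param tol relative convergence tolerance on the coefficient vector and
#'   on the common component (default `1e-8`).
#' @param max_iter iteration cap (default 1000); non-convergence returns the
#'   last iterate with `converged = FALSE` and a warning.
#' @return an object of class `factor_model_fit` with elements `beta`,
#'   `tau`, `intercept`, `unit_effects`, `time_effects`, `factors` (`T x R`),
#'   `loadings` (`n x R`), `fitted`, `residuals`, `R`, `converged`,
#'   `n_iter`, `objective`, and the internal within design (for inference).
#' @export
fit_ife <- function(outcome, covariates = NULL, R, exposure = NULL,
                    tol = 1e-8, max_iter = 1000L) {
  Y <- as.matrix(outcome)
  n <- nrow(Y); T_ <- ncol(Y)
  R <- as.integer(R)
  if (R < 0L || R > min(n, T_) - 1L)
    stop("R must satisfy 0 <= R <= min(n, T) - 1")
  if (is.list(covariates) && !is.array(covariates))
    covariates <- simplify2array_cov(covariates, n, T_)
  if (is.null(covariates)) covariates <- array(numeric(0), dim = c(n, T_, 0))
  if (is.matrix(covariates)) covariates <- array(covariates, dim = c(n, T_, 1))
  k <- dim(covariates)[3]

  xmats <- covariate_list(covariates)
  has_tau <- !is.null(exposure)
  if (has_tau) xmats <- c(list(exposure), xmats)
  design <- within_design(xmats)
  p <- length(design$keep)

  C <- matrix(0, n, T_)
  coef_old <- rep(Inf, p)
  C_old <- C
  converged <- FALSE
  n_iter <- 0L
  sv <- NULL
  repeat {
    n_iter <- n_iter + 1L
    sol <- within_solve(design, Y - C)
    # residual matrix net of covariates/treatment and additive effects
    fitted_x <- fitted_from_coef(design, sol$coef, xmats, n, T_)
    eff <- additive_effects(Y - fitted_x - C)
    W <- Y - fitted_x - eff$intercept - eff$unit_effects -
      rep(eff$time_effects, each = n)
    if (R > 0L) {
      sv <- svd(W, nu = R, nv = R)
      d <- sv$d[seq_len(R)]
      C <- sv$u %*% (d * t(sv$v))
    } else C <- matrix(0, n, T_)

    dc <- if (p) max(abs(sol$coef - coef_old)) / (1 + max(abs(sol$coef))) else 0
    dC <- sqrt(sum((C - C_old)^2)) / (1 + sqrt(sum(C_old^2)))
    coef_old <- sol$coef; C_old <- C
    if (max(dc, dC) < tol || R == 0L) { converged <- TRUE; break }
    if (n_iter >= max_iter) break
  }
  if (!converged)
    warning("iterative principal components did not converge in ",
            max_iter, " iterations")

  sol <- within_solve(design, Y - C)
  fitted_x <- fitted_from_coef(design, sol$coef, xmats, n, T_)
  eff <- additive_effects(Y - fitted_x - C)
  fitted <- fitted_x + eff$intercept + eff$unit_effects +
    rep(eff$time_effects, each = n) + C
  resid <- Y - fitted

  tau <- NA_real_
  beta <- rep(NA_real_, k)
  coef_full <- rep(0, length(xmats))
  coef_full[design$keep] <- sol$coef
  if (has_tau) {
    if (!(1L %in% design$keep))
      stop("treatment indicator is collinear with the fixed effects; tau not identified")
    tau <- coef_full[1]
    beta_raw <- coef_full[-1]
  } else beta_raw <- coef_full
  kept_cov <- setdiff(design$keep, if (has_tau) 1L else integer(0)) -
    (if (has_tau) 1L else 0L)
  beta[kept_cov] <- beta_raw[kept_cov]
  beta[setdiff(seq_len(k), kept_cov)] <- if (k) NA_real_ else numeric(0)

  if (R > 0L) {
    d <- sv$d[seq_len(R)]
    factors <- sqrt(T_) * sv$v                      # T x R, Lambda'Lambda/T = I
    loadings <- sv$u %*% diag(d, R, R) / sqrt(T_)   # n x R, M'M diagonal
  } else {
    factors <- matrix(numeric(0), T_, 0)
    loadings <- matrix(numeric(0), n, 0)
  }
  structure(
    list(beta = beta, tau = tau,
         intercept = eff$intercept,
         unit_effects = eff$unit_effects, time_effects = eff$time_effects,
         factors = factors, loadings = loadings,
         fitted = fitted, residuals = resid,
         R = R, converged = converged, n_iter = n_iter,
         objective = sum(resid^2),
         design = design, n_covariates = k, has_tau = has_tau),
    class = "factor_model_fit")
}

fitted_from_coef <- function(design, coef, xmats, n, T_) {
  F <- matrix(0, n, T_)
  for (j in seq_along(design$keep))
    F <- F + coef[j] * xmats[[design$keep[j]]]
  F
}

simplify2array_cov <- function(lst, n, T_) {
  a <- array(NA_real_, dim = c(n, T_, length(lst)))
  for (j in seq_along(lst)) a[, , j] <- lst[[j]]
  a
}

#' @export
print.factor_model_fit <- function(x, ...) {
  cat("Interactive fixed effects fit: R = ", x$R,
      ", ", ifelse(x$converged, "converged", "NOT converged"),
      " in ", x$n_iter, " iterations\n", sep = "")
  if (x$has_tau) cat("  tau = ", format(x$tau, digits = 5), "\n", sep = "")
  if (length(x$beta)) cat("  beta = ",
                          paste(format(x$beta, digits = 5), collapse = " "),
                          "\n", sep = "")
  cat("  SSR = ", format(x$objective, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Cross-validated choice of the number of interactive factors
#'
#' For each candidate factor count `R`, fits the factor model on the control
#' units over the full sample period, then holds out one treated
#' pre-treatment period at a time: treated loadings are projected from the
#' remaining pre periods and the held-out treated outcomes are predicted.
#' The chosen `R` minimizes the accumulated mean squared prediction error;
#' ties break toward the smaller `R`. This targets exactly the quantity the
#' counterfactual methods need — out-of-sample prediction of treated
#' outcomes in the absence of treatment.
#'
#' Candidates are capped so the leave-one-out projection stays determined:
#' `R <= last_pre - 2` (the projection uses `R` factors plus a unit
#' intercept on `last_pre - 1` retained pre periods).
#'
#' @param panel a [panel_dataset()].
#' @param R_max largest candidate factor count (default 5).
#' @return an object of class `cv_result`: `candidate_R`, `mspe`,
#'   `chosen_R`.
#' @export
choose_factors_cv <- function(panel, R_max = 5L) {
  validate_panel(panel)
  tp <- panel$last_pre
  grp <- split_groups(panel)
  ctrl <- grp$control; trt <- grp$treated
  n_ctrl <- nrow(ctrl$outcome)
  feas_max <- min(R_max, tp - 2L, n_ctrl - 1L, n_periods(panel) - 1L)
  if (feas_max < 0L)
    stop("insufficient pre-treatment periods for cross-validation; ",
         "feasible R_max would be ", max(tp - 2L, -1L))
  candidates <- 0:feas_max
  mspe <- numeric(length(candidates))
  for (ci in seq_along(candidates)) {
    R <- candidates[ci]
    cf <- fit_ife(ctrl$outcome, ctrl$covariates, R = R)
    err <- 0; m <- 0L
    for (s in seq_len(tp)) {
      keep <- setdiff(seq_len(tp), s)
      pr <- project_loadings_idx(trt$outcome, trt$covariates, cf, keep)
      pred <- predict_factor_outcome(trt$covariates, cf, pr, s)
      err <- err + sum((trt$outcome[, s] - pred)^2)
      m <- m + length(pred)
    }
    mspe[ci] <- err / m
  }
  chosen <- candidates[which.min(mspe)]
  structure(list(candidate_R = candidates, mspe = mspe, chosen_R = chosen),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Factor-count cross-validation\n")
  print(data.frame(R = x$candidate_R, mspe = x$mspe))
  cat("chosen R =", x$chosen_R, "\n")
  invisible(x)
}

#' ATT by interactive fixed effects
#'
#' Fits the factor model on all units with a homogeneous treatment
#' coefficient \eqn{\tau}; the ATT estimate is \eqn{\hat\tau}. Standard
#' errors are cluster-robust over units, treating the estimated factor
#' structure as known regressors (factor-estimation uncertainty is ignored,
#' a known understatement documented in the methods vignette).
#'
#' @param panel a [panel_dataset()].
#' @param R number of interactive factors, or `"cv"` to select by
#'   [choose_factors_cv()].
#' @param R_max cap for cross-validation when `R = "cv"`.
#' @param level confidence level.
#' @return an [att_result()] with `method = "ife"`; diagnostics include the
#'   chosen `R`, the CV path when applicable, and the full fit.
#' @export
estimate_ife_att <- function(panel, R = "cv", R_max = 5L, level = 0.95) {
  validate_panel(panel)
  cv <- NULL
  if (identical(R, "cv")) {
    cv <- choose_factors_cv(panel, R_max = R_max)
    R <- cv$chosen_R
  }
  fit <- fit_ife(panel$outcome, panel$covariates, R = R,
                 exposure = panel$exposure)
  n <- n_units(panel); T_ <- n_periods(panel)
  # additive + factor structure parameters counted in the df correction
  n_fe <- 1L + (n - 1L) + (T_ - 1L) + fit$R * (n + T_)
  n_fe <- min(n_fe, n * T_ - length(fit$design$keep) - 1L)
  V <- cluster_vcov_within(fit$design, fit$residuals, n_fe)
  se <- sqrt(V[1, 1])
  df <- n - 1
  p <- 2 * stats::pt(-abs(fit$tau / se), df)
  q <- stats::qt(1 - (1 - level) / 2, df)
  post <- post_periods(panel)
  att_result("ife", fit$tau, att_by_period = rep(fit$tau, length(post)),
             se = se, ci_low = fit$tau - q * se, ci_high = fit$tau + q * se,
             p_value = p, inference_method = "cluster_robust",
             diagnostics = list(R = fit$R, cv = cv, fit = fit,
                                last_pre = panel$last_pre))
}
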