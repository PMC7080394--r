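#' Scenario configuration for the Monte Carlo benchmark
#'
#' Defines one cell of the simulation design comparing the four ATT
#' estimators. The data-generating process is
#' \deqn{Y_{it} = X_{it}\beta + \mu_{i1} + \lambda_{1t}
#'   + \lambda_{2t}\mu_{i2} + \lambda_{3t}\mu_{i3}
#'   + D_{it}\tau_{it} + \varepsilon_{it}}
#' over a fixed horizon of `T_total` periods whose last `T_post` are
#' post-treatment. \eqn{X_i, \mu_{i1}, \mu_{i2}, \mu_{i3}} are standard
#' normal draws with the \eqn{\mu} means shifted up by `mean_shift` (2
#' standard deviations) for treated units; \eqn{\lambda_{1t} \sim U(0,5)};
#' \eqn{X_{it} = 0.5 X_i + 0.5 N(0,1)}; \eqn{\varepsilon_{it}} is standard
#' normal (optionally AR(1) with coefficient `ar1_rho`).
#'
#' Scenarios:
#' \describe{
#'   \item{A}{parallel trends: \eqn{\lambda_{2t} = \lambda_{3t} = 0}.}
#'   \item{B}{nonparallel trends: \eqn{\lambda_{2t} = 0.2t},
#'     \eqn{\lambda_{3t} = 0.1t} in absolute time.}
#'   \item{C}{as B, but the covariate is the time-invariant \eqn{X_i} and a
#'     `hull_fraction` share of control units gets \eqn{\mu_2, \mu_3} raised
#'     by `hull_shift` standard deviations, placing the average treated unit
#'     inside the donor convex hull.}
#'   \item{D}{as B, plus an additive post-treatment shock `shock` affecting
#'     only treated units.}
#'   \item{E}{as B with imbalanced group sizes (default 10 treated / 100
#'     control).}
#' }
#' Effects: homogeneous \eqn{\tau_{it} = 1}; heterogeneous
#' \eqn{\tau_{it} = 1 + (\mu_{i1} - 2)} (population mean 1 for treated
#' units).
#'
#' @param scenario one of `"A"`..`"E"`.
#' @param effect `"homogeneous"` or `"heterogeneous"`.
#' @param T_pre number of retained pre-treatment periods (the most recent
#'   ones before the post block; absolute time indices are kept in the
#'   trend terms).
#' @param n_treated,n_control group sizes (scenario E overrides the defaults
#'   with 10/100 unless set explicitly).
#' @param T_total,T_post horizon length and post-block length.
#' @param trend_slopes slopes of the two interacted trend factors.
#' @param mean_shift treated-group shift of the \eqn{\mu} means, in SD.
#' @param hull_fraction,hull_shift scenario-C controls: share of control
#'   units shifted and the size of the shift, in SD.
#' @param shock scenario-D treated-only post-period shock.
#' @param beta covariate coefficient.
#' @param ar1_rho AR(1) coefficient of the idiosyncratic error (0 = iid).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("A", "B", "C", "D", "E"),
                            effect = c("homogeneous", "heterogeneous"),
                            T_pre = 18L,
                            n_treated = NULL, n_control = NULL,
                            T_total = 22L, T_post = 4L,
                            trend_slopes = c(0.2, 0.1),
                            mean_shift = 2, hull_fraction = 0.25,
                            hull_shift = 4, shock = 2, beta = 1,
                            ar1_rho = 0) {
  scenario <- match.arg(scenario)
  effect <- match.arg(effect)
  if (is.null(n_treated)) n_treated <- if (scenario == "E") 10L else 62L
  if (is.null(n_control)) n_control <- if (scenario == "E") 100L else 49L
  T_pre <- as.integer(T_pre)
  if (T_pre < 2L) stop("T_pre must be at least 2")
  if (T_pre + T_post > T_total)
    stop("T_pre + T_post must not exceed T_total")
  if (hull_fraction < 0 || hull_fraction > 1)
    stop("hull_fraction must lie in [0, 1]")
  structure(
    list(scenario = scenario, effect = effect, T_pre = T_pre,
         n_treated = as.integer(n_treated), n_control = as.integer(n_control),
         T_total = as.integer(T_total), T_post = as.integer(T_post),
         trend_slopes = trend_slopes, mean_shift = mean_shift,
         hull_fraction = hull_fraction, hull_shift = hull_shift,
         shock = shock, beta = beta, ar1_rho = ar1_rho),
    class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario ", x$scenario, ifelse(x$effect == "homogeneous", "1", "2"),
      ": ", x$n_treated, " treated / ", x$n_control, " control, T_pre = ",
      x$T_pre, ", post = ", x$T_post, " of ", x$T_total, " periods\n",
      sep = "")
  invisible(x)
}

# Short label like "B1" used in summaries.
scenario_label <- function(config) {
  paste0(config$scenario, ifelse(config$effect == "homogeneous", "1", "2"))
}

#' Generate one simulated panel
#'
#' Draws a panel from the scenario's data-generating process over the full
#' `T_total` horizon (post = the final `T_post` periods), then truncates to
#' the `T_pre` pre periods immediately preceding the post block. The trend
#' factors use absolute time indices, so shortening `T_pre` discards early
#' periods without re-indexing the trends.
#'
#' @param config a [scenario_config()].
#' @param rep_seed integer seed for this replicate.
#' @return object of class `simulated_panel`: `panel` (a
#'   [panel_dataset()]), `true_effects` (treated x post matrix of
#'   \eqn{\tau_{it}}), `true_att` (their mean, the per-replicate estimand).
#' @export
generate_panel <- function(config, rep_seed) {
  stopifnot(inherits(config, "scenario_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(rep_seed))

  n1 <- config$n_treated; n0 <- config$n_control
  n <- n1 + n0
  T_ <- config$T_total
  treated <- c(rep(1, n1), rep(0, n0))

  Xi <- stats::rnorm(n)
  mu1 <- stats::rnorm(n) + config$mean_shift * treated
  mu2 <- stats::rnorm(n) + config$mean_shift * treated
  mu3 <- stats::rnorm(n) + config$mean_shift * treated
  if (config$scenario == "C") {
    n_shift <- round(config$hull_fraction * n0)
    shift_idx <- n1 + sample.int(n0, n_shift)
    mu2[shift_idx] <- mu2[shift_idx] + config$hull_shift
    mu3[shift_idx] <- mu3[shift_idx] + config$hull_shift
  }

  lambda1 <- stats::runif(T_, 0, 5)
  tt <- seq_len(T_)
  if (config$scenario == "A") {
    lambda2 <- rep(0, T_); lambda3 <- rep(0, T_)
  } else {
    lambda2 <- config$trend_slopes[1] * tt
    lambda3 <- config$trend_slopes[2] * tt
  }

  X <- if (config$scenario == "C") {
    matrix(Xi, n, T_)                            # time-invariant covariate
  } else {
    0.5 * Xi + 0.5 * matrix(stats::rnorm(n * T_), n, T_)
  }

  eps <- matrix(stats::rnorm(n * T_), n, T_)
  if (config$ar1_rho != 0) {
    # stationary AR(1) with unit marginal variance
    rho <- config$ar1_rho
    for (t in 2:T_)
      eps[, t] <- rho * eps[, t - 1] + sqrt(1 - rho^2) * eps[, t]
  }

  tp_abs <- T_ - config$T_post                    # absolute last pre period
  D <- outer(treated, as.numeric(tt > tp_abs))
  tau_unit <- if (config$effect == "homogeneous") rep(1, n) else 1 + (mu1 - config$mean_shift)
  tau_mat <- D * tau_unit

  Y <- config$beta * X + mu1 + rep(lambda1, each = n) +
    outer(mu2, lambda2) + outer(mu3, lambda3) + tau_mat + eps
  if (config$scenario == "D") Y <- Y + config$shock * D

  keep <- seq(tp_abs - config$T_pre + 1L, T_)
  panel <- panel_dataset(Y[, keep, drop = FALSE], treated,
                         last_pre = config$T_pre,
                         covariates = X[, keep, drop = FALSE],
                         time_ids = tt[keep])
  post_cols <- which(keep > tp_abs)
  true_effects <- tau_mat[treated == 1, keep[post_cols], drop = FALSE]
  structure(
    list(panel = panel, true_effects = true_effects,
         true_att = mean(true_effects),
         config = config, rep_seed = as.integer(rep_seed)),
    class = "simulated_panel")
}

#' Apply one estimator to a panel, returning the point ATT
#'
#' Thin dispatcher used by the Monte Carlo harness; inference is skipped.
#'
#' @param method one of `"did"`, `"sc"`, `"ife"`, `"gsc"`.
#' @param panel a [panel_dataset()].
#' @param opts named list of tuning options: `ife_r`, `gsc_r` (factor count
#'   or `"cv"`), `r_max`, `sc_n_starts`, `sc_maxit`.
#' @return numeric ATT point estimate.
#' @export
apply_method <- function(method, panel, opts = list()) {
  switch(method,
    did = fit_did(panel)$att,
    sc  = estimate_sc_att(panel, inference = "none",
                          n_starts = opts$sc_n_starts %||% 3L,
                          maxit = opts$sc_maxit %||% 150L)$att,
    ife = estimate_ife_att(panel, R = opts$ife_r %||% "cv",
                           R_max = opts$r_max %||% 5L)$att,
    gsc = estimate_gsc_att(panel, R = opts$gsc_r %||% "cv",
                           R_max = opts$r_max %||% 5L,
                           inference = "none")$att,
    stop("unknown method: ", method))
}

#' Run the Monte Carlo comparison
#'
#' For each replicate, one panel is generated per configuration (with
#' `rep_seed = base_seed + r`) and every requested method is applied to the
#' same panel; per-replicate errors are \eqn{\hat\tau_{ATT} - ATT_{true}},
#' where the truth is the per-replicate sample mean of the generated
#' \eqn{\tau_{it}} over treated units and post periods. Method failures are
#' caught, logged and counted; a (method, scenario) cell failing on more
#' than 5% of replicates is flagged invalid in the summary.
#'
#' @param configs a [scenario_config()] or list of them.
#' @param methods character subset of `c("did", "sc", "ife", "gsc")`.
#' @param n_reps replicates per configuration (default 500).
#' @param base_seed integer master seed.
#' @param opts named list of per-method tuning options (see
#'   `apply_method` internals): `ife_r`, `gsc_r`, `r_max`, `sc_n_starts`,
#'   `sc_maxit`.
#' @param verbose print progress every 10 replicates.
#' @return object of class `simulation_result`: the per-replicate estimate
#'   table (`per_rep`) and the aggregated [summarize_study()] table
#'   (`summary`).
#' @export
run_study <- function(configs, methods, n_reps = 500L, base_seed,
                      opts = list(), verbose = FALSE) {
  if (inherits(configs, "scenario_config")) configs <- list(configs)
  stopifnot(length(configs) >= 1L, length(methods) >= 1L)
  methods <- match.arg(methods, c("did", "sc", "ife", "gsc"),
                       several.ok = TRUE)
  rows <- vector("list", length(configs) * n_reps * length(methods))
  ri <- 0L
  for (cfg in configs) {
    lab <- scenario_label(cfg)
    for (r in seq_len(n_reps)) {
      sim <- generate_panel(cfg, rep_seed = base_seed + r)
      for (m in methods) {
        est <- tryCatch(apply_method(m, sim$panel, opts),
                        error = function(e) NA_real_)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          method = m, scenario = lab, effect = cfg$effect,
          T_pre = cfg$T_pre, rep = r,
          estimate = est, true_att = sim$true_att,
          error = est - sim$true_att)
      }
      if (verbose && r %% 10L == 0L)
        message(lab, " T_pre=", cfg$T_pre, ": replicate ", r, "/", n_reps)
    }
  }
  per_rep <- do.call(rbind, rows)
  structure(list(per_rep = per_rep, summary = summarize_study(per_rep),
                 base_seed = base_seed, n_reps = n_reps),
            class = "simulation_result")
}

#' Aggregate per-replicate estimates into the benchmark summary
#'
#' One row per (method, scenario, effect, T_pre) with mean percentage bias
#' (`100 * mean(error)` relative to the unit-size true effect), mean squared
#' error, its square root, the Monte Carlo standard error of the mean
#' squared error (SD of squared errors / sqrt(n)), and failure counts.
#'
#' @param per_rep the per-replicate data frame from [run_study()].
#' @return data frame of class `simulation_summary`.
#' @export
summarize_study <- function(per_rep) {
  if (inherits(per_rep, "simulation_result")) per_rep <- per_rep$per_rep
  keys <- unique(per_rep[c("method", "scenario", "effect", "T_pre")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- per_rep$method == keys$method[i] &
      per_rep$scenario == keys$scenario[i] &
      per_rep$effect == keys$effect[i] &
      per_rep$T_pre == keys$T_pre[i]
    err <- per_rep$error[sel]
    ok <- is.finite(err)
    n_fail <- sum(!ok)
    err <- err[ok]
    mse <- mean(err^2)
    data.frame(
      method = keys$method[i], scenario = keys$scenario[i],
      effect = keys$effect[i], T_pre = keys$T_pre[i],
      mean_bias_pct = 100 * mean(err),
      mean_squared_error = mse,
      rmse = sqrt(mse),
      mc_se = if (length(err) > 1) stats::sd(err^2) / sqrt(length(err)) else NA_real_,
      n_reps = length(err), n_failed = n_fail,
      valid = n_fail <= 0.05 * (length(err) + n_fail))
  }))
  class(out) <- c("simulation_summary", "data.frame")
  out
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat("Monte Carlo comparison of ATT estimators\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
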