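test_that("controls-only fit reproduces a noiseless factor model over all periods", {
  fp <- factor_panel(noise = 0, delta = 3)
  cf <- fit_controls(fp$panel, R = 2)
  expect_lt(max(abs(cf$residuals)), 1e-6)
  # factors are estimated for every period, post included
  expect_equal(nrow(cf$factors), n_periods(fp$panel))
})

test_that("loading projection is exact for units generated from the control model", {
  fp <- factor_panel(noise = 0, delta = 3)
  cf <- fit_controls(fp$panel, R = 2)
  trt <- split_groups(fp$panel)$treated
  pr <- project_loadings(trt$outcome[, 1:8], NULL, cf, pre_idx = 1:8)
  # the projected common component must reproduce the treated pre outcomes
  recon <- pr$unit_intercepts +
    pr$loadings %*% t(cf$factors[1:8, ]) +
    rep(cf$intercept + cf$time_effects[1:8], each = 5)
  expect_equal(recon, trt$outcome[, 1:8], tolerance = 1e-6,
               ignore_attr = TRUE)
  # underdetermined projection is refused
  expect_error(project_loadings(trt$outcome[, 1:2], NULL, cf, pre_idx = 1:2),
               "underdetermined")
})

test_that("orthonormal factor block makes the projection a closed-form inner product", {
  set.seed(8)
  tp <- 6
  lam_raw <- qr.Q(qr(matrix(rnorm(tp * 2), tp, 2)))   # orthonormal columns
  cfit <- structure(list(R = 2L, beta = numeric(0),
                         intercept = 0, time_effects = rep(0, tp),
                         factors = lam_raw), class = "factor_model_fit")
  y <- matrix(rnorm(tp), 1, tp)
  ydm <- y - mean(y)
  pr <- project_loadings(y, NULL, cfit, pre_idx = 1:tp)
  # intercept + orthogonal projection: loadings solve jointly with the mean,
  # compare against explicit least squares
  X <- cbind(1, lam_raw)
  cf <- solve(crossprod(X), crossprod(X, as.numeric(y)))
  expect_equal(as.numeric(pr$loadings), cf[-1], tolerance = 1e-10)
  expect_equal(pr$unit_intercepts, cf[1], tolerance = 1e-10)
})

test_that("GSC recovers an additive effect exactly on noiseless rank-2 data", {
  fp <- factor_panel(noise = 0, delta = 3)
  g <- gsc_fit(fp$panel, R = 2)
  expect_equal(g$att, 3, tolerance = 1e-8)
  expect_lt(abs(g$pre_mean_gap), 1e-8)
  expect_equal(g$effects, matrix(3, 5, 4), tolerance = 1e-8,
               ignore_attr = TRUE)
  # treated loadings identified exactly (up to the estimated rotation):
  # common components must agree
  cf <- g$control_fit
  expect_equal(g$treated_loadings %*% t(cf$factors) +
                 g$treated_intercepts + rep(cf$intercept + cf$time_effects,
                                            each = 5),
               fp$mu[1:5, ] %*% t(fp$lam), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("GSC with R = 0 reduces to two-way prediction from controls", {
  p <- toy_panel(n = 12, T_ = 9, last_pre = 6, n_treated = 3, noise = 0.4,
                 k = 0, seed = 19)
  g <- gsc_fit(p, R = 0)
  expect_equal(ncol(g$treated_loadings), 0)
  # counterfactual = control time effects + unit intercept fitted on pre
  ctrl <- split_groups(p)$control
  trt <- split_groups(p)$treated
  tmean <- colMeans(ctrl$outcome)
  for (i in 1:3) {
    shift <- mean(trt$outcome[i, 1:6] - tmean[1:6])
    expect_equal(g$counterfactual[i, ], tmean + shift, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("per-unit counterfactuals make GSC invariant to effect heterogeneity", {
  # same panels, homogeneous vs heterogeneous effects: the estimation error
  # against the per-panel sample truth is identical
  cfg1 <- scenario_config("A", "homogeneous", T_pre = 6,
                          n_treated = 10, n_control = 15, T_total = 10)
  cfg2 <- scenario_config("A", "heterogeneous", T_pre = 6,
                          n_treated = 10, n_control = 15, T_total = 10)
  e1 <- vapply(1:5, function(r) {
    s <- generate_panel(cfg1, r)
    gsc_fit(s$panel, R = 0)$att - s$true_att
  }, numeric(1))
  e2 <- vapply(1:5, function(r) {
    s <- generate_panel(cfg2, r)
    gsc_fit(s$panel, R = 0)$att - s$true_att
  }, numeric(1))
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("parametric bootstrap is reproducible, sane, and demands a seed", {
  p <- toy_panel(n = 14, T_ = 9, last_pre = 6, n_treated = 4, noise = 0.5,
                 k = 0, seed = 23)
  g <- gsc_fit(p, R = 0)
  b1 <- parametric_bootstrap(p, g, B = 30, seed = 5)
  b2 <- parametric_bootstrap(p, g, B = 30, seed = 5)
  expect_identical(b1$draws, b2$draws)
  expect_equal(b1$se, sd(b1$draws))
  expect_true(b1$p_value >= 0 && b1$p_value <= 1)
  expect_equal(b1$ci_high - b1$ci_low, 2 * 1.96 * b1$se, tolerance = 1e-12)
  expect_error(parametric_bootstrap(p, g, B = 1, seed = 1), "at least 2")
  expect_error(parametric_bootstrap(p, g, B = 10), "seed")
  r <- estimate_gsc_att(p, R = 0, inference = "bootstrap", B = 30, seed = 5)
  expect_equal(r$se, b1$se)
})
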