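test_that("donor weight QP handles exact-match, interpolation and boundary cases", {
  # treated equals donor 2 exactly -> all weight there, objective 0
  X0 <- cbind(c(1, 4, 2), c(3, 0, 5), c(2, 2, 2))
  w <- solve_donor_weights(c(3, 0, 5), X0)
  expect_equal(as.numeric(w), c(0, 1, 0), tolerance = 1e-8)
  expect_equal(attr(w, "objective"), 0, tolerance = 1e-10)
  # scalar midpoint interpolation
  w <- solve_donor_weights(1.5, matrix(c(1, 2), 1, 2))
  expect_equal(as.numeric(w), c(0.5, 0.5), tolerance = 1e-8)
  # treated outside the hull: boundary vertex, objective 9
  w <- solve_donor_weights(5, matrix(c(1, 2), 1, 2))
  expect_equal(as.numeric(w), c(0, 1), tolerance = 1e-8)
  expect_equal(attr(w, "objective"), 9, tolerance = 1e-8)
  # errors
  expect_error(solve_donor_weights(1, matrix(1, 1, 1)), "2 donor")
  expect_error(solve_donor_weights(1:2, matrix(1, 3, 2)), "dimensions")
  expect_error(solve_donor_weights(1:2, matrix(1, 2, 2), c(0, 0)),
               "degenerate")
})

test_that("the simplex QP agrees with an independent NNLS-based reference", {
  skip_if_not_installed("pracma")
  set.seed(33)
  for (rep in 1:5) {
    X0 <- matrix(rnorm(24), 6, 4)
    x1 <- rnorm(6)
    w_ours <- solve_donor_weights(x1, X0)
    # reference: penalty-row NNLS (Lawson-Hanson) enforcing sum-to-one
    pen <- 1e5
    w_ref <- pracma::lsqnonneg(rbind(X0 / sqrt(6), rep(pen, 4)),
                               c(x1 / sqrt(6), pen))$x
    w_ref <- w_ref / sum(w_ref)
    obj <- function(w) mean((x1 - as.numeric(X0 %*% w))^2)
    expect_lte(obj(w_ours), obj(w_ref) + 1e-8)
    expect_equal(as.numeric(w_ours), w_ref, tolerance = 1e-4)
  }
})

test_that("QP solution matches a simplex grid-search oracle on small problems", {
  set.seed(101)
  for (J in c(2, 3)) {
    for (rep in 1:6) {
      p <- sample(2:4, 1)
      X0 <- matrix(rnorm(p * J, sd = 2), p, J)
      x1 <- rnorm(p, sd = 2)
      v <- runif(p); v <- v / sum(v)
      w <- solve_donor_weights(x1, X0, v)
      oracle <- grid_search_weights(x1, X0, v)
      expect_lte(attr(w, "objective"), oracle$objective + 1e-4)
      expect_equal(as.numeric(w), oracle$weights, tolerance = 5e-3)
    }
  }
})

test_that("weights stay on the simplex and the solution beats every vertex", {
  set.seed(7)
  X0 <- matrix(rnorm(40), 5, 8)
  x1 <- rnorm(5)
  w <- solve_donor_weights(x1, X0)
  expect_true(all(w >= -1e-10 & w <= 1 + 1e-10))
  expect_equal(sum(w), 1, tolerance = 1e-6)
  vertex_objs <- vapply(seq_len(8), function(j)
    sum((x1 - X0[, j])^2) / 5, numeric(1))
  expect_lte(attr(w, "objective"), min(vertex_objs) + 1e-10)
})

test_that("nested V/W optimization never fits worse than equal predictor weights", {
  set.seed(21)
  for (rep in 1:4) {
    p <- toy_panel(n = 10, T_ = 9, last_pre = 6, n_treated = 1, k = 0,
                   noise = 1, seed = 30 + rep)
    w <- optimize_predictor_weights(p, n_starts = 3, maxit = 60)
    g <- split_groups(p)
    x1 <- g$treated$outcome[1, 1:6]
    X0 <- t(g$control$outcome[, 1:6])
    w_eq <- solve_donor_weights(x1, X0)
    mspe_eq <- mean((x1 - as.numeric(X0 %*% w_eq))^2)
    expect_lte(w$pre_rmspe^2, mspe_eq + 1e-10)
    expect_equal(sum(w$predictor_weights), 1, tolerance = 1e-8)
    expect_true(all(w$predictor_weights >= 0))
  }
})

test_that("a perfect donor yields exact effect recovery and zero pre-RMSPE", {
  set.seed(3)
  T_ <- 10; tp <- 7
  base <- cumsum(rnorm(T_))
  Y <- rbind(base + c(rep(0, tp), rep(2.5, T_ - tp)),  # treated = donor1 + shift
             base,
             base + 3,
             rnorm(T_))
  p <- panel_dataset(Y, c(1, 0, 0, 0), tp)
  r <- estimate_sc_att(p, inference = "none")
  expect_equal(r$diagnostics$pre_rmspe, 0, tolerance = 1e-6)
  expect_equal(r$att, 2.5, tolerance = 1e-6)
  expect_equal(unname(r$att_by_period), rep(2.5, 3), tolerance = 1e-6)
})

test_that("SC att is invariant to control relabeling and synthetic path is hull-bounded", {
  p <- toy_panel(n = 9, T_ = 10, last_pre = 7, n_treated = 3, noise = 0.8,
                 k = 0, seed = 55)
  r1 <- estimate_sc_att(p, inference = "none", n_starts = 1)
  perm <- c(1:3, sample(4:9))
  p2 <- panel_dataset(p$outcome[perm, ], p$treated[perm], p$last_pre)
  r2 <- estimate_sc_att(p2, inference = "none", n_starts = 1)
  expect_equal(r1$att, r2$att, tolerance = 1e-6)
  # convex combination bound per period
  g <- split_groups(average_treated(p))
  w <- r1$diagnostics$weights$donor_weights
  synth <- as.numeric(t(g$control$outcome) %*% w)
  expect_true(all(synth <= apply(g$control$outcome, 2, max) + 1e-8))
  expect_true(all(synth >= apply(g$control$outcome, 2, min) - 1e-8))
})

test_that("placebo rank p-value follows the (1 + #{>=}) / (1 + J) formula", {
  set.seed(9)
  T_ <- 10; tp <- 7; J <- 9
  Y0 <- matrix(rnorm(J * T_, sd = 0.5), J, T_)
  treated <- c(5 + cumsum(rnorm(T_, sd = 0.1)))
  treated[(tp + 1):T_] <- treated[(tp + 1):T_] + 25   # huge post shift
  p <- panel_dataset(rbind(treated, Y0), c(1, rep(0, J)), tp)
  r <- estimate_sc_att(p, inference = "placebo", n_starts = 1)
  plc <- r$diagnostics$placebo
  expect_s3_class(plc, "placebo_distribution")
  expect_length(plc$unit_statistics, J)
  # treated ratio strictly largest -> smallest attainable p
  expect_true(plc$treated_statistic > max(plc$unit_statistics))
  expect_equal(r$p_value, 1 / (J + 1))
  # and a treated unit indistinguishable from noise gets a large p
  p0 <- panel_dataset(rbind(Y0[1, ], Y0[-1, ]), c(1, rep(0, J - 1)), tp)
  r0 <- estimate_sc_att(p0, inference = "placebo", n_starts = 1)
  expect_gte(r0$p_value, 1 / J)
  expect_lte(r0$p_value, 1)
})

test_that("zero pre-RMSPE placebo units get infinite ratios with a warning", {
  T_ <- 8; tp <- 5
  base <- sin(seq_len(T_))
  # control 2 is exactly reproducible from controls 3 and 4 pre AND post:
  Y <- rbind(base + 2,                 # treated
             c(base[1:tp], 9, 9, 9),  # placebo with perfect pre fit, wild post
             base, base,              # duplicate donors
             base * 2)
  p <- panel_dataset(Y, c(1, 0, 0, 0, 0), tp)
  warns <- capture_warnings(plc <- placebo_inference(p, treated_statistic = 1,
                                                     n_starts = 1))
  expect_true(any(grepl("zero pre-treatment RMSPE", warns)))
  expect_true(any(is.infinite(plc$unit_statistics)))
})
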