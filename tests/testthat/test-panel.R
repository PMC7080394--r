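test_that("panel construction validates shapes, flags and the exposure block", {
  p <- panel_dataset(rbind(c(1, 2, 3), c(4, 5, 6)), c(1, 0), 2)
  expect_s3_class(p, "panel_dataset")
  expect_equal(n_units(p), 2)
  expect_equal(n_periods(p), 3)
  expect_equal(p$exposure, outer(c(1, 0), c(0, 0, 1)))

  expect_error(panel_dataset(rbind(c(1, NA), c(1, 2)), c(1, 0), 1),
               "non-finite")
  expect_error(panel_dataset(rbind(c(1, 2), c(1, 2)), c(1, 2), 1), "binary")
  expect_error(panel_dataset(rbind(c(1, 2), c(1, 2)), c(1, 1), 1), "control")
  expect_error(panel_dataset(rbind(c(1, 2), c(1, 2)), c(0, 0), 1), "treated")
  expect_error(panel_dataset(rbind(c(1, 2), c(1, 2)), c(1, 0), 2),
               "last_pre")
  # tampering with the exposure matrix is caught
  p$exposure[1, 1] <- 1
  expect_error(validate_panel(p), "block adoption")
})

test_that("load_panel reads long CSVs, re-indexes periods, and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  dat <- expand.grid(hospital = c("u1", "u2"), quarter = c(3, 1, 2))
  dat$y <- seq_len(6) / 2
  dat$grp <- ifelse(dat$hospital == "u1", 1, 0)
  dat$age <- rnorm(6)
  write.csv(dat, tmp, row.names = FALSE)
  map <- list(unit = "hospital", time = "quarter", outcome = "y",
              treated = "grp", covariates = "age", last_pre = 2)
  p <- load_panel(tmp, map)
  expect_equal(n_units(p), 2)
  expect_equal(n_periods(p), 3)
  expect_equal(p$time_ids, c(1, 2, 3))        # sorted, order-preserving
  expect_equal(p$last_pre, 2L)
  # value round trip up to row order
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, tmp2, covariate_names = "age")
  p2 <- load_panel(tmp2, list(unit = "unit", time = "time", outcome = "outcome",
                              treated = "treated", covariates = "age",
                              last_pre = 2))
  expect_equal(p2$outcome, p$outcome)
  expect_equal(p2$covariates, p$covariates)
  expect_equal(p2$treated, p$treated)

  # unbalanced panel: the offending unit/period is named
  write.csv(dat[-2, ], tmp, row.names = FALSE)
  expect_error(load_panel(tmp, map), "u2.*3|missing row")
  # mapping errors
  expect_error(load_panel(tmp2, list(unit = "unit", time = "time",
                                     outcome = "nope", treated = "treated",
                                     last_pre = 2)), "nope")
  expect_error(load_panel(tmp2, modifyList(map, list(unit = "unit", time = "time",
                                                     outcome = "outcome",
                                                     treated = "treated",
                                                     covariates = NULL,
                                                     last_pre = 99))),
               "not an observed period")
})

test_that("mapping can come from a JSON or YAML config file", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  p0 <- toy_panel(k = 0)
  write_panel(p0, tmp)
  cfg <- list(unit = "unit", time = "time", outcome = "outcome",
              treated = "treated", last_pre = 5)
  jf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jf, auto_unbox = TRUE)
  yf <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yf)
  expect_equal(load_panel(tmp, jf)$outcome, p0$outcome)
  expect_equal(load_panel(tmp, yf)$outcome, p0$outcome)
})

test_that("average_treated collapses treated units to their mean and controls stay", {
  Y <- rbind(c(1, 5), c(3, 7), c(0, 1), c(2, 2))
  p <- panel_dataset(Y, c(1, 1, 0, 0), 1)
  a <- average_treated(p)
  expect_equal(sum(a$treated), 1)
  expect_equal(a$outcome[1, ], c(2, 6))          # arithmetic means
  expect_equal(a$outcome[2:3, ], Y[3:4, ])       # controls untouched
  # single treated unit: identity
  p1 <- panel_dataset(Y, c(1, 0, 0, 0), 1)
  expect_equal(average_treated(p1)$outcome, p1$outcome)
  # commutes with per-period affine maps of the outcome
  aff <- function(panel) {
    sc <- c(2, -1); off <- c(3, 0.5)
    panel_dataset(sweep(sweep(panel$outcome, 2, sc, "*"), 2, off, "+"),
                  panel$treated, panel$last_pre)
  }
  expect_equal(average_treated(aff(p))$outcome, aff(average_treated(p))$outcome)
})

test_that("split_groups partitions units and preserves all periods", {
  p <- toy_panel(n = 5, n_treated = 1, k = 0)
  g <- split_groups(p)
  expect_equal(nrow(g$treated$outcome), 1)
  expect_equal(nrow(g$control$outcome), 4)
  expect_equal(ncol(g$control$outcome), n_periods(p))
  # recombining reproduces the original (treated first in toy_panel)
  expect_equal(rbind(g$treated$outcome, g$control$outcome), p$outcome)
  expect_equal(c(g$treated$treated, g$control$treated), p$treated)
  # exposure block structure preserved
  expect_equal(g$treated$exposure,
               p$exposure[p$treated == 1, , drop = FALSE])
  expect_true(all(g$control$exposure == 0))
})
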