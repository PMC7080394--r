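#' Balanced pre-post panel dataset
#'
#' Constructs and validates a balanced panel of `n` units observed over `T`
#' consecutive periods, with a single block treatment adoption: every treated
#' unit is exposed in all periods after the designated last pre-treatment
#' period `last_pre`, and never before. This is the common input type of all
#' four ATT estimators in the package.
#'
#' @param outcome numeric `n x T` matrix of outcomes \eqn{Y_{it}} (units in
#'   rows, periods in columns).
#' @param treated binary vector of length `n`; 1 marks units exposed to the
#'   intervention in post periods.
#' @param last_pre integer index \eqn{t'} of the final pre-treatment period
#'   (`1 <= last_pre < T`); periods `last_pre + 1, ..., T` are post.
#' @param covariates optional numeric `n x T x k` array of time-varying
#'   covariates \eqn{X_{it}}. A time-invariant covariate is stored by
#'   repeating its value across periods; downstream estimators drop the
#'   resulting collinear column after the within transformation.
#' @param unit_ids,time_ids optional identifier vectors (length `n` / `T`).
#'
#' @return An object of class `panel_dataset`: a list with elements
#'   `outcome`, `covariates`, `treated`, `last_pre`, `unit_ids`, `time_ids`,
#'   and the derived `exposure` matrix \eqn{D_{it} = D_i \cdot 1[t > t']}.
#' @export
panel_dataset <- function(outcome, treated, last_pre, covariates = NULL,
                          unit_ids = NULL, time_ids = NULL) {
  outcome <- as.matrix(outcome)
  n <- nrow(outcome)
  T_ <- ncol(outcome)
  if (is.null(unit_ids)) unit_ids <- if (!is.null(rownames(outcome))) rownames(outcome) else as.character(seq_len(n))
  if (is.null(time_ids)) time_ids <- seq_len(T_)
  if (is.null(covariates)) {
    covariates <- array(numeric(0), dim = c(n, T_, 0))
  } else if (is.matrix(covariates)) {
    covariates <- array(covariates, dim = c(n, T_, 1))
  }
  treated <- as.numeric(treated)
  last_pre <- as.integer(last_pre)
  x <- structure(
    list(outcome = unname(outcome), covariates = covariates,
         treated = treated, last_pre = last_pre,
         unit_ids = unit_ids, time_ids = time_ids,
         exposure = outer(treated, as.numeric(seq_len(T_) > last_pre))),
    class = "panel_dataset")
  validate_panel(x)
  x
}

#' Validate a panel_dataset
#'
#' Checks balance (all cells finite), the binary treatment flag, group sizes
#' (at least one treated and one control unit), `1 <= last_pre < T`, and that
#' the exposure matrix is exactly the outer product of the treatment flag and
#' the post-period indicator (block adoption, no staggering).
#'
#' @param x a `panel_dataset`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_panel <- function(x) {
  stopifnot(inherits(x, "panel_dataset"))
  n <- nrow(x$outcome); T_ <- ncol(x$outcome)
  if (n < 2L || T_ < 2L)
    stop("panel must have at least 2 units and 2 periods")
  if (!all(is.finite(x$outcome)))
    stop("unbalanced or invalid panel: non-finite outcome cells present")
  if (length(dim(x$covariates)) != 3L ||
      !all(dim(x$covariates)[1:2] == c(n, T_)))
    stop("covariates must be an n x T x k array matching the outcome")
  if (dim(x$covariates)[3] > 0 && !all(is.finite(x$covariates)))
    stop("unbalanced or invalid panel: non-finite covariate cells present")
  if (length(x$treated) != n || !all(x$treated %in% c(0, 1)))
    stop("treated flag must be a binary (0/1) vector of length n")
  if (sum(x$treated) < 1)
    stop("panel must contain at least one treated unit")
  if (sum(1 - x$treated) < 1)
    stop("panel must contain at least one control unit")
  if (x$last_pre < 1L || x$last_pre >= T_)
    stop("last_pre must satisfy 1 <= last_pre < T (t' = ", x$last_pre,
         ", T = ", T_, ")")
  expo <- outer(x$treated, as.numeric(seq_len(T_) > x$last_pre))
  if (!isTRUE(all.equal(unname(x$exposure), expo)))
    stop("exposure matrix must equal treated_flag x post-indicator (block adoption)")
  if (length(x$unit_ids) != n || length(x$time_ids) != T_)
    stop("unit_ids/time_ids lengths must match the outcome matrix")
  invisible(x)
}

#' @export
print.panel_dataset <- function(x, ...) {
  n <- nrow(x$outcome); T_ <- ncol(x$outcome)
  cat("panel_dataset: ", n, " units x ", T_, " periods",
      " (", sum(x$treated), " treated / ", sum(1 - x$treated), " control)\n",
      sep = "")
  cat("  last pre-treatment period: t' = ", x$last_pre,
      " (", T_ - x$last_pre, " post periods)\n", sep = "")
  k <- dim(x$covariates)[3]
  cat("  covariates: k = ", k, "\n", sep = "")
  invisible(x)
}

#' Number of units / periods in a panel
#' @param panel a `panel_dataset`.
#' @return integer count.
#' @export
n_units <- function(panel) nrow(panel$outcome)

#' @rdname n_units
#' @export
n_periods <- function(panel) ncol(panel$outcome)

#' Post-treatment period indices
#' @param panel a `panel_dataset`.
#' @return integer vector of post (resp. pre) period indices.
#' @export
post_periods <- function(panel) seq(panel$last_pre + 1L, ncol(panel$outcome))

#' @rdname post_periods
#' @export
pre_periods <- function(panel) seq_len(panel$last_pre)

#' Read a long-format panel from a delimited text file
#'
#' Reads a CSV with one row per (unit, period) and assembles a validated
#' [panel_dataset()]. Periods are re-indexed to consecutive integers `1..T`
#' preserving their sorted order; original period values are kept as
#' `time_ids`.
#'
#' @param path path to a delimited text file.
#' @param mapping either a named list with elements `unit`, `time`,
#'   `outcome`, `treated` (column names), optionally `covariates` (character
#'   vector of column names) and `last_pre` (the *value* of the final
#'   pre-treatment period in the time column), or a path to a JSON/YAML file
#'   holding that list.
#' @param sep field separator passed to [utils::read.csv()].
#' @return a `panel_dataset`.
#' @export
load_panel <- function(path, mapping, sep = ",") {
  mapping <- resolve_mapping(mapping)
  dat <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  for (f in c("unit", "time", "outcome", "treated")) {
    if (is.null(mapping[[f]]))
      stop("mapping must name the '", f, "' column")
    if (!mapping[[f]] %in% names(dat))
      stop("column '", mapping[[f]], "' (", f, ") not found in ", path)
  }
  covs <- mapping$covariates
  if (!is.null(covs) && !all(covs %in% names(dat)))
    stop("covariate column(s) not found: ",
         paste(setdiff(covs, names(dat)), collapse = ", "))

  unit <- dat[[mapping$unit]]
  time <- dat[[mapping$time]]
  unit_ids <- unique(unit)
  time_ids <- sort(unique(time))
  n <- length(unit_ids); T_ <- length(time_ids)
  i <- match(unit, unit_ids)
  t <- match(time, time_ids)

  # balance check with a named offender
  counts <- matrix(0L, n, T_)
  counts[cbind(i, t)] <- counts[cbind(i, t)] + 1L
  dup <- which(tabulate((t - 1L) * n + i, n * T_) > 1L)
  if (length(dup))
    stop("duplicate rows for unit '", unit_ids[(dup[1] - 1L) %% n + 1L],
         "', period '", time_ids[(dup[1] - 1L) %/% n + 1L], "'")
  miss <- which(counts == 0L, arr.ind = TRUE)
  if (nrow(miss))
    stop("unbalanced panel: missing row for unit '", unit_ids[miss[1, 1]],
         "', period '", time_ids[miss[1, 2]], "'")

  outcome <- matrix(NA_real_, n, T_)
  outcome[cbind(i, t)] <- dat[[mapping$outcome]]
  k <- length(covs)
  covariates <- array(NA_real_, dim = c(n, T_, k))
  for (j in seq_len(k)) {
    slice <- matrix(NA_real_, n, T_)
    slice[cbind(i, t)] <- dat[[covs[j]]]
    covariates[, , j] <- slice
  }
  flag_raw <- dat[[mapping$treated]]
  if (!all(flag_raw %in% c(0, 1)))
    stop("treated flag column '", mapping$treated, "' must be binary 0/1")
  flag <- numeric(n)
  flag[i] <- flag_raw
  per_unit <- tapply(flag_raw, i, function(v) length(unique(v)))
  if (any(per_unit > 1))
    stop("treated flag varies within unit '",
         unit_ids[as.integer(names(per_unit)[per_unit > 1][1])],
         "' (staggered or time-varying adoption is not supported)")

  if (is.null(mapping$last_pre))
    stop("mapping must provide 'last_pre' (the final pre-treatment period value)")
  tp <- match(mapping$last_pre, time_ids)
  if (is.na(tp))
    stop("last_pre value '", mapping$last_pre, "' is not an observed period")
  panel_dataset(outcome, flag, tp, covariates = if (k) covariates else NULL,
                unit_ids = as.character(unit_ids), time_ids = time_ids)
}

resolve_mapping <- function(mapping) {
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- if (grepl("\\.ya?ml$", mapping, ignore.case = TRUE))
      yaml::read_yaml(mapping)
    else jsonlite::read_json(mapping, simplifyVector = TRUE)
  }
  if (!is.list(mapping)) stop("mapping must be a list or a JSON/YAML file path")
  mapping
}

#' Write a panel to a long-format CSV
#'
#' Inverse of [load_panel()] up to row order: columns `unit`, `time`,
#' `outcome`, `treated`, plus one column per covariate slice.
#'
#' @param panel a `panel_dataset`.
#' @param path output file path.
#' @param covariate_names optional names for the covariate columns
#'   (default `X1..Xk`).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, covariate_names = NULL) {
  validate_panel(panel)
  n <- n_units(panel); T_ <- n_periods(panel)
  k <- dim(panel$covariates)[3]
  if (is.null(covariate_names)) covariate_names <- paste0("X", seq_len(k))
  out <- data.frame(
    unit = rep(panel$unit_ids, times = T_),
    time = rep(panel$time_ids, each = n),
    outcome = as.vector(panel$outcome),
    treated = rep(panel$treated, times = T_))
  for (j in seq_len(k))
    out[[covariate_names[j]]] <- as.vector(panel$covariates[, , j])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Collapse the treated group to a single averaged pseudo-unit
#'
#' Replaces all treated units by one pseudo-unit whose outcome and covariates
#' at each period are the unweighted means across treated units; control
#' units are unchanged. This is the preprocessing step of the synthetic
#' control estimator when several units adopt the intervention together.
#'
#' @param panel a `panel_dataset` with at least one treated unit.
#' @return a `panel_dataset` with one treated unit (placed first).
#' @export
average_treated <- function(panel) {
  validate_panel(panel)
  tr <- panel$treated == 1
  if (!any(tr)) stop("panel has no treated units")
  if (sum(tr) == 1L && which(tr) == 1L) return(panel)
  k <- dim(panel$covariates)[3]
  y_avg <- colMeans(panel$outcome[tr, , drop = FALSE])
  outcome <- rbind(y_avg, panel$outcome[!tr, , drop = FALSE])
  covariates <- array(NA_real_, dim = c(nrow(outcome), n_periods(panel), k))
  T_ <- n_periods(panel)
  for (j in seq_len(k)) {
    covariates[, , j] <- rbind(
      colMeans(matrix(panel$covariates[tr, , j], sum(tr), T_)),
      matrix(panel$covariates[!tr, , j], sum(!tr), T_))
  }
  panel_dataset(outcome,
                treated = c(1, rep(0, sum(!tr))),
                last_pre = panel$last_pre,
                covariates = if (k) covariates else NULL,
                unit_ids = c("treated_avg", panel$unit_ids[!tr]),
                time_ids = panel$time_ids)
}

#' Partition a panel into treated and control sub-panels
#'
#' @param panel a `panel_dataset`.
#' @return list with elements `treated` and `control`, each retaining all
#'   `T` periods. The control sub-panel keeps the treatment flag at zero for
#'   every unit (one flag is left formally treated only when a sub-panel
#'   would otherwise fail validation is *not* done here; instead the raw
#'   pieces are returned unclassed when a side has no opposite group).
#' @export
split_groups <- function(panel) {
  validate_panel(panel)
  tr <- panel$treated == 1
  list(treated = subset_units(panel, which(tr)),
       control = subset_units(panel, which(!tr)))
}

# Raw (unvalidated) unit subset: a one-group slice is not itself a valid
# pre-post panel, so the slice keeps class "panel_slice".
subset_units <- function(panel, idx) {
  k <- dim(panel$covariates)[3]
  structure(
    list(outcome = panel$outcome[idx, , drop = FALSE],
         covariates = panel$covariates[idx, , , drop = FALSE],
         treated = panel$treated[idx],
         last_pre = panel$last_pre,
         unit_ids = panel$unit_ids[idx],
         time_ids = panel$time_ids,
         exposure = panel$exposure[idx, , drop = FALSE]),
    class = "panel_slice")
}
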