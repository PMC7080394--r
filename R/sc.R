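#' Solve the simplex-constrained donor-weight quadratic program
#'
#' Finds donor weights \eqn{W} minimizing
#' \eqn{(X_1 - X_0 W)' V (X_1 - X_0 W)} subject to \eqn{w_j \ge 0} and
#' \eqn{\sum_j w_j = 1}, where \eqn{X_1} holds the treated unit's predictor
#' values, the columns of \eqn{X_0} the donors', and the diagonal \eqn{V}
#' the predictor-importance weights.
#'
#' The program is solved by accelerated projected gradient descent with
#' exact Euclidean projection onto the unit simplex (fixed step `1/L`),
#' followed by an exact equality-constrained least-squares refinement on
#' the active (positive-weight) set.
#'
#' @param predictors_treated numeric vector \eqn{X_1} (length `p`).
#' @param predictors_controls numeric `p x J` matrix \eqn{X_0}, one column
#'   per donor (`J >= 2`).
#' @param predictor_weights nonnegative vector of length `p` (normalized
#'   internally to sum to 1); default equal weights.
#' @param max_iter projected-gradient iteration budget (fallback path).
#' @param w_start optional feasible warm start (defaults to equal weights).
#' @param tol relative convergence tolerance of the fallback path.
#' @return numeric vector of `J` donor weights on the unit simplex, with the
#'   attained objective as attribute `"objective"`.
#' @export
solve_donor_weights <- function(predictors_treated, predictors_controls,
                                predictor_weights = NULL,
                                max_iter = 3000L, w_start = NULL,
                                tol = 1e-12) {
  x1 <- as.numeric(predictors_treated)
  X0 <- as.matrix(predictors_controls)
  p <- length(x1); J <- ncol(X0)
  if (nrow(X0) != p) stop("predictor dimensions of treated and donors disagree")
  if (J < 2L) stop("at least 2 donor units are required")
  if (is.null(predictor_weights)) predictor_weights <- rep(1, p)
  v <- as.numeric(predictor_weights)
  if (length(v) != p || any(v < 0)) stop("predictor_weights must be nonnegative, length p")
  if (sum(v) <= 0) stop("degenerate predictor weights: all zero")
  v <- v / sum(v)

  sv <- sqrt(v)
  A <- X0 * sv
  b <- x1 * sv
  G <- crossprod(A)
  gv <- as.numeric(crossprod(A, b))
  w <- simplex_qp_active_set(G, gv, w_start = w_start)
  if (is.null(w))   # rare degenerate cycling: projected-gradient fallback
    w <- simplex_ls(A, b, max_iter = max_iter, w_start = w_start, tol = tol)
  if (any(!is.finite(w)))
    stop("donor weight QP failed to converge (non-finite solution)")

  # exact equality-constrained refinement on the active set
  act <- which(w > 1e-10)
  if (length(act) >= 1L) {
    As <- A[, act, drop = FALSE]
    m <- length(act)
    K <- rbind(cbind(2 * crossprod(As), rep(1, m)), c(rep(1, m), 0))
    rhs <- c(2 * crossprod(As, b), 1)
    ws <- tryCatch(solve(K, rhs)[seq_len(m)], error = function(e) NULL)
    if (!is.null(ws) && all(ws >= -1e-9)) {
      w2 <- numeric(J)
      w2[act] <- pmax(ws, 0)
      w2 <- w2 / sum(w2)
      if (sc_objective(x1, X0, v, w2) <= sc_objective(x1, X0, v, w)) w <- w2
    }
  }
  attr(w, "objective") <- sc_objective(x1, X0, v, w)
  w
}

sc_objective <- function(x1, X0, v, w) {
  d <- x1 - as.numeric(X0 %*% w)
  sum(v * d^2)
}

# Exact primal active-set solver for min 1/2 w'Gw - g'w on the unit
# simplex. Solves the equality-constrained KKT system on the current
# support, steps to the first nonnegativity boundary when the candidate
# leaves the feasible set, and adds the most KKT-violating index otherwise.
# Supports in synthetic-control problems are small, so this typically
# terminates in a handful of linear solves. Returns NULL if the iteration
# cap is hit (caller falls back to projected gradient).
simplex_qp_active_set <- function(G, g, w_start = NULL, itmax = NULL) {
  J <- length(g)
  if (is.null(itmax)) itmax <- 20L + 10L * J
  scal <- mean(abs(diag(G))) + 1e-300
  if (is.null(w_start)) {
    j0 <- which.min(0.5 * diag(G) - g)
    w <- numeric(J); w[j0] <- 1
  } else {
    w <- pmax(as.numeric(w_start), 0)
    w <- if (sum(w) > 0) w / sum(w) else {
      j0 <- which.min(0.5 * diag(G) - g)
      ww <- numeric(J); ww[j0] <- 1; ww
    }
  }
  S <- which(w > 1e-12)
  solve_support <- function(S) {
    m <- length(S)
    K <- rbind(cbind(G[S, S, drop = FALSE], rep(1, m)), c(rep(1, m), 0))
    rhs <- c(g[S], 1)
    tryCatch(solve(K, rhs), error = function(e) {
      K[seq_len(m), seq_len(m)] <- K[seq_len(m), seq_len(m)] +
        1e-9 * scal * diag(m)
      tryCatch(solve(K, rhs), error = function(e2) NULL)
    })
  }
  for (it in seq_len(itmax)) {
    sol <- solve_support(S)
    if (is.null(sol)) return(NULL)
    wS <- sol[seq_along(S)]
    if (any(wS < -1e-12)) {
      cur <- w[S]
      d <- wS - cur
      bad <- which(d < -1e-300 & wS < 0)
      alpha <- min(1, -cur[bad] / d[bad])
      cur <- pmax(cur + alpha * d, 0)
      w <- numeric(J); w[S] <- cur
      drop_idx <- S[cur <= 1e-12]
      S <- setdiff(S, drop_idx)
      if (!length(S)) return(NULL)
      next
    }
    w <- numeric(J); w[S] <- wS
    grad <- as.numeric(G %*% w) - g
    lam <- -mean(grad[S])
    viol <- grad + lam
    j <- which.min(viol)
    if (viol[j] >= -1e-9 * (scal + abs(lam))) return(w)
    if (j %in% S) return(w)
    S <- sort(c(S, j))
  }
  NULL
}

# Exact Euclidean projection onto the unit simplex (sort-based).
project_simplex <- function(v) {
  u <- sort.int(v, decreasing = TRUE, method = "quick")
  css <- cumsum(u)
  rho <- max(which(u > (css - 1) / seq_along(u)))
  pmax(v - (css[rho] - 1) / rho, 0)
}

# min ||A w - b||^2 over the unit simplex by accelerated projected gradient
# (FISTA) with a fixed step 1/L, L the largest eigenvalue of A'A. Cost per
# iteration is one J x J matrix-vector product, so the run time is
# deterministic regardless of conditioning.
simplex_ls <- function(A, b, max_iter = 3000L, tol = 1e-12, w_start = NULL) {
  J <- ncol(A)
  G <- crossprod(A)
  g <- as.numeric(crossprod(A, b))
  # power iteration for the top eigenvalue (cheaper than a full eigen)
  u <- rep(1 / sqrt(J), J)
  for (i in 1:30) {
    u2 <- as.numeric(G %*% u)
    nu <- sqrt(sum(u2^2))
    if (nu < 1e-300) break
    u <- u2 / nu
  }
  L <- max(sum(u * as.numeric(G %*% u)), 1e-12) * 1.01
  w <- if (is.null(w_start)) rep(1 / J, J) else w_start
  y <- w
  t_k <- 1
  qobj <- function(w) sum(w * as.numeric(G %*% w)) / 2 - sum(g * w)
  obj_prev <- qobj(w)
  for (it in seq_len(max_iter)) {
    w_new <- project_simplex(y - (as.numeric(G %*% y) - g) / L)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    y <- w_new + ((t_k - 1) / t_new) * (w_new - w)
    w <- w_new
    t_k <- t_new
    if (it %% 25L == 0L) {
      obj_now <- qobj(w)
      if (obj_now > obj_prev) {       # momentum overshoot: restart
        y <- w
        t_k <- 1
      } else if (obj_prev - obj_now < tol * (1 + abs(obj_now))) break
      obj_prev <- obj_now
    }
  }
  w
}

#' Nested predictor-weight and donor-weight optimization
#'
#' Synthetic control weight selection with all pre-treatment outcomes as
#' predictors: an outer search over the normalized diagonal predictor
#' weights `V` (multi-start Nelder-Mead on the log scale: equal-weights
#' start plus random restarts), an inner donor-weight QP
#' ([solve_donor_weights()]) for each candidate `V`, and as outer objective
#' the mean squared pre-period outcome discrepancy between the treated and
#' synthetic unit. Only improvements over the equal-weights baseline are
#' accepted, so the result never fits the pre-period outcomes worse than
#' equal predictor weights.
#'
#' @param panel a [panel_dataset()] whose treated group is a single
#'   (averaged) unit; see [average_treated()].
#' @param n_starts number of outer starts (1 = equal weights only).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return an object of class `sc_weights`: `donor_weights`,
#'   `predictor_weights`, `predictors_treated`, `predictors_controls`,
#'   `pre_rmspe`, `donor_ids`.
#' @export
optimize_predictor_weights <- function(panel, n_starts = 3L, maxit = 150L) {
  validate_panel(panel)
  if (sum(panel$treated) != 1L)
    stop("panel must contain a single (averaged) treated unit; see average_treated()")
  tp <- panel$last_pre
  if (tp < 2L) stop("at least 2 pre-treatment periods are required as predictors")
  grp <- split_groups(panel)
  x1 <- grp$treated$outcome[1, seq_len(tp)]
  Y0_pre <- grp$control$outcome[, seq_len(tp), drop = FALSE]
  X0 <- t(Y0_pre)                                   # p x J
  if (ncol(X0) < 2L) stop("at least 2 donor units are required")

  # warm-started, budget-limited inner solves during the outer search; the
  # returned weights are recomputed at full precision below
  w_prev <- rep(1 / ncol(X0), ncol(X0))
  outer_obj <- function(v) {
    w <- solve_donor_weights(x1, X0, v, max_iter = 400L, w_start = w_prev,
                             tol = 1e-9)
    w_prev <<- as.numeric(w)
    mean((x1 - as.numeric(X0 %*% w))^2)
  }
  best_v <- rep(1 / tp, tp)
  best_val <- outer_obj(best_v)
  if (n_starts >= 1L && tp > 1L) {
    starts <- list(rep(0, tp))
    if (n_starts > 1L)
      starts <- c(starts, replicate(n_starts - 1L,
                                    stats::rnorm(tp, sd = 1), simplify = FALSE))
    for (s in starts) {
      opt <- stats::optim(s, function(lv) {
        lv <- lv - max(lv)
        outer_obj(exp(lv) / sum(exp(lv)))
      }, method = "Nelder-Mead", control = list(maxit = maxit))
      v <- exp(opt$par - max(opt$par))
      v <- v / sum(v)
      val <- outer_obj(v)
      if (val < best_val) { best_val <- val; best_v <- v }
    }
  }
  w <- solve_donor_weights(x1, X0, best_v)
  structure(
    list(donor_weights = as.numeric(w),
         predictor_weights = best_v,
         predictors_treated = x1,
         predictors_controls = X0,
         pre_rmspe = sqrt(best_val),
         donor_ids = grp$control$unit_ids),
    class = "sc_weights")
}

#' @export
print.sc_weights <- function(x, digits = 4, ...) {
  cat("Synthetic control weights (", length(x$donor_weights), " donors, ",
      length(x$predictors_treated), " pre-period predictors)\n", sep = "")
  nz <- which(x$donor_weights > 1e-4)
  cat("  non-zero donors:\n")
  for (j in nz)
    cat("    ", x$donor_ids[j], ": ",
        format(x$donor_weights[j], digits = digits), "\n", sep = "")
  cat("  pre-treatment RMSPE: ", format(x$pre_rmspe, digits = digits), "\n",
      sep = "")
  invisible(x)
}

#' ATT by the synthetic control method
#'
#' Averages the treated units into a single pseudo-unit, selects donor and
#' predictor weights on the pre-treatment outcomes
#' ([optimize_predictor_weights()]), and estimates the per-period effect as
#' the gap \eqn{\hat\tau_{1t} = Y_{1t} - \sum_j w_j Y_{jt}} for each post
#' period; the ATT is their average. Inference is by in-space placebo
#' tests ([placebo_inference()]).
#'
#' @param panel a [panel_dataset()].
#' @param inference `"placebo"` or `"none"`.
#' @param n_starts,maxit outer-search controls, see
#'   [optimize_predictor_weights()].
#' @return an [att_result()] with `method = "sc"`; diagnostics include the
#'   `sc_weights`, the post/pre RMSPE ratio, and (with placebo inference)
#'   the `placebo_distribution`.
#' @export
estimate_sc_att <- function(panel, inference = c("placebo", "none"),
                            n_starts = 3L, maxit = 150L) {
  inference <- match.arg(inference)
  validate_panel(panel)
  avg <- average_treated(panel)
  w <- optimize_predictor_weights(avg, n_starts = n_starts, maxit = maxit)
  grp <- split_groups(avg)
  post <- post_periods(avg)
  synth <- as.numeric(t(grp$control$outcome) %*% w$donor_weights)
  gaps <- grp$treated$outcome[1, ] - synth
  att <- mean(gaps[post])
  post_rmspe <- sqrt(mean(gaps[post]^2))
  ratio <- if (w$pre_rmspe > 0) post_rmspe / w$pre_rmspe else Inf
  plc <- NULL
  p <- NA_real_
  if (inference == "placebo") {
    plc <- placebo_inference(panel, treated_statistic = ratio,
                             n_starts = n_starts, maxit = maxit)
    p <- plc$p_value
  }
  att_result("sc", att, att_by_period = gaps[post],
             p_value = p,
             inference_method = if (inference == "placebo") "placebo" else "none",
             diagnostics = list(weights = w, gaps = gaps,
                                pre_rmspe = w$pre_rmspe,
                                post_pre_ratio = ratio,
                                placebo = plc, last_pre = panel$last_pre))
}

#' In-space placebo inference for synthetic control
#'
#' Each control unit in turn is cast as a pseudo-treated unit, a synthetic
#' control is built from the remaining controls with the same nested weight
#' optimization, and the post/pre RMSPE ratio is recorded. The p-value ranks
#' the treated unit's ratio in this null distribution:
#' \deqn{p = \frac{1 + \#\{j : r_j \ge r_{treated}\}}{1 + J}.}
#' Ties count against the treated unit. A placebo with a zero pre-treatment
#' RMSPE gets an infinite ratio (with a warning), which also counts against
#' the treated unit.
#'
#' @param panel the original [panel_dataset()] (>= 2 control units).
#' @param treated_statistic the treated unit's post/pre RMSPE ratio; if
#'   `NULL`, it is recomputed by running the SC pipeline.
#' @param n_starts,maxit outer-search controls.
#' @return object of class `placebo_distribution`: `unit_statistics` (one
#'   ratio per control), `treated_statistic`, `p_value`.
#' @export
placebo_inference <- function(panel, treated_statistic = NULL,
                              n_starts = 3L, maxit = 150L) {
  validate_panel(panel)
  ctrl_idx <- which(panel$treated == 0)
  J <- length(ctrl_idx)
  if (J < 2L) stop("placebo inference requires at least 2 control units")
  if (is.null(treated_statistic)) {
    res <- estimate_sc_att(panel, inference = "none",
                           n_starts = n_starts, maxit = maxit)
    treated_statistic <- res$diagnostics$post_pre_ratio
  }
  tp <- panel$last_pre
  post <- post_periods(panel)
  ratios <- numeric(J)
  for (jj in seq_len(J)) {
    j <- ctrl_idx[jj]
    donors <- setdiff(ctrl_idx, j)
    sub <- subset_units(panel, c(j, donors))
    pseudo <- panel_dataset(sub$outcome,
                            treated = c(1, rep(0, length(donors))),
                            last_pre = tp,
                            covariates = if (dim(sub$covariates)[3])
                              sub$covariates else NULL,
                            unit_ids = sub$unit_ids,
                            time_ids = sub$time_ids)
    w <- optimize_predictor_weights(pseudo, n_starts = n_starts,
                                    maxit = maxit)
    synth <- as.numeric(t(sub$outcome[-1, , drop = FALSE]) %*% w$donor_weights)
    gaps <- sub$outcome[1, ] - synth
    pre_r <- sqrt(mean(gaps[seq_len(tp)]^2))
    post_r <- sqrt(mean(gaps[post]^2))
    if (pre_r == 0) {
      warning("placebo unit '", panel$unit_ids[j],
              "' has zero pre-treatment RMSPE; ratio set to +Inf")
      ratios[jj] <- Inf
    } else ratios[jj] <- post_r / pre_r
  }
  p <- (1 + sum(ratios >= treated_statistic)) / (1 + J)
  structure(
    list(unit_statistics = ratios, treated_statistic = treated_statistic,
         p_value = p, unit_ids = panel$unit_ids[ctrl_idx]),
    class = "placebo_distribution")
}
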