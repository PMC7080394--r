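#' ATT estimation result
#'
#' Container returned by every estimator: the average treatment effect on
#' the treated (ATT) over post periods, per-post-period effects, and an
#' inference summary whose meaning depends on the estimator (cluster-robust
#' Wald for DiD/IFE, in-space placebo rank for SC, parametric bootstrap for
#' GSC).
#'
#' @param method one of `"did"`, `"sc"`, `"ife"`, `"gsc"`.
#' @param att numeric scalar ATT.
#' @param att_by_period numeric vector of per-post-period average effects.
#' @param se,ci_low,ci_high,p_value optional inference quantities.
#' @param inference_method one of `"cluster_robust"`, `"placebo"`,
#'   `"bootstrap"`, `"none"`.
#' @param diagnostics free-form named list (e.g. chosen factor count,
#'   pre-fit RMSPE).
#' @return an object of class `att_result`.
#' @export
att_result <- function(method, att, att_by_period,
                       se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       p_value = NA_real_,
                       inference_method = "none", diagnostics = list()) {
  stopifnot(method %in% c("did", "sc", "ife", "gsc"))
  if (is.finite(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value must lie in [0, 1]")
  if (is.finite(ci_low) && is.finite(ci_high) &&
      !(ci_low <= att + 1e-12 && att <= ci_high + 1e-12))
    stop("confidence interval must contain the point estimate")
  structure(
    list(method = method, att = att, att_by_period = att_by_period,
         se = se, ci_low = ci_low, ci_high = ci_high, p_value = p_value,
         inference_method = inference_method, diagnostics = diagnostics),
    class = "att_result")
}

#' @export
print.att_result <- function(x, digits = 4, ...) {
  lab <- c(did = "Difference-in-differences", sc = "Synthetic control",
           ife = "Interactive fixed effects", gsc = "Generalized synthetic control")
  cat(lab[[x$method]], " ATT estimate\n", sep = "")
  cat("  ATT: ", format(x$att, digits = digits), sep = "")
  if (is.finite(x$se)) cat("  (se ", format(x$se, digits = digits), ")", sep = "")
  cat("\n")
  if (is.finite(x$ci_low))
    cat("  95% CI: [", format(x$ci_low, digits = digits), ", ",
        format(x$ci_high, digits = digits), "]\n", sep = "")
  if (is.finite(x$p_value))
    cat("  p-value: ", format.pval(x$p_value, digits = digits),
        " (", x$inference_method, ")\n", sep = "")
  cat("  per-period effects: ",
      paste(format(x$att_by_period, digits = digits), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Serialize an att_result to CSV
#'
#' Writes the one-row summary (`method, att, se, ci_low, ci_high, p_value`)
#' and, optionally, a per-post-period effects file.
#'
#' @param x an `att_result`.
#' @param path output CSV path.
#' @param by_period_path optional path for the per-period effects CSV.
#' @return `path`, invisibly.
#' @export
write_att_result <- function(x, path, by_period_path = NULL) {
  utils::write.csv(att_result_row(x), path, row.names = FALSE)
  if (!is.null(by_period_path)) {
    utils::write.csv(
      data.frame(period = seq_along(x$att_by_period) +
                   (x$diagnostics$last_pre %||% 0),
                 effect = x$att_by_period),
      by_period_path, row.names = FALSE)
  }
  invisible(path)
}

att_result_row <- function(x) {
  data.frame(method = x$method, att = x$att, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value,
             inference = x$inference_method)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
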