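#' Time-varying excess risk of the intervention
#'
#' Evaluates the excess risk
#' \eqn{ER(t) = (\exp(\hat\beta_X + \hat\beta_{Xns}^T ns(t)) - 1) \times
#' 100\%} — the percentage change in relative risk attributable to the
#' intervention — with pointwise 95% confidence intervals from the delta
#' method on the log scale: \eqn{SE(t) = \sqrt{(1, ns(t))\, V\, (1,
#' ns(t))^T}} where V is the joint covariance block of the intervention main
#' effect and its spline interaction under the chosen correction, and
#' \eqn{CI = (\exp(\hat\eta \pm z_{0.975} SE) - 1) \times 100}.
#'
#' The point estimate depends only on the GLM fit, so naive, UB and MSRC
#' curves differ only through their interval widths.
#'
#' @param fit A `pd_glm` fit of a count series built from
#'   [build_rti_design()] columns.
#' @param vcov_obj A `pd_covariance` from [ub_correct()]/[msrc_correct()],
#'   or a plain covariance matrix (e.g. [naive_covariance()]) with rows and
#'   columns matching the fit's terms.
#' @param design The design tibble (carries the time-spline basis).
#' @param times Evaluation times (day index within the study); must lie
#'   inside the spline boundary.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble of class `er_curve`: `time`, `er_pct`, `ci_lo`, `ci_hi`,
#'   `se_log`, `method`.
#' @export
excess_risk_curve <- function(fit, vcov_obj, design, times,
                              conf_level = 0.95) {
  stopifnot(inherits(fit, "pd_glm"))
  icols <- attr(design, "intervention_cols")
  if (is.null(icols)) {
    stop("`design` must come from build_rti_design().", call. = FALSE)
  }
  if (inherits(vcov_obj, "pd_covariance")) {
    V <- vcov_obj$G_n
    method <- vcov_obj$method
  } else {
    V <- as.matrix(vcov_obj)
    method <- "GLM"
  }
  terms <- colnames(fit$x)
  idx <- match(icols, terms)
  if (anyNA(idx)) {
    stop("Fit is missing intervention columns: ",
         paste(icols[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  b <- fit$beta_hat[idx]
  Vb <- V[idx, idx, drop = FALSE]
  rows <- cbind(1, .time_basis_at(design, times))
  eta <- drop(rows %*% b)
  se <- sqrt(pmax(rowSums((rows %*% Vb) * rows), 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    time = times,
    er_pct = 100 * expm1(eta),
    ci_lo = 100 * expm1(eta - z * se),
    ci_hi = 100 * expm1(eta + z * se),
    se_log = se,
    method = method
  )
  class(out) <- c("er_curve", class(out))
  out
}

#' Plot an excess-risk curve
#'
#' Excess risk over time with its confidence ribbon; multiple methods (rows
#' bound together) are coloured separately.
#'
#' @param object An `er_curve` tibble (possibly several methods row-bound).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.er_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$er_pct)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi,
                   fill = .data$method), alpha = 0.25
    ) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$method)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "day", y = "excess risk (%)",
                  colour = "method", fill = "method")
}
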