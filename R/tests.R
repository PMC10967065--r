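#' Two-sided Wald test of a single coefficient
#'
#' @param estimate Coefficient estimate.
#' @param se Its standard error (> 0).
#' @param level Nominal test size (default 0.05).
#' @return A list with `z`, `p`, `reject`.
#' @examples
#' wald_test(0.4, 0.1)
#' @export
wald_test <- function(estimate, se, level = 0.05) {
  stopifnot(se > 0)
  z <- estimate / se
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = p, reject = abs(z) > stats::qnorm(1 - level / 2))
}

#' Joint 2-df chi-square test of the intervention terms
#'
#' Tests the level-change and trend-change coefficients jointly:
#' \eqn{(\hat\beta_X, \hat\beta_{X(t-t_0)})^T V^{-1} (\hat\beta_X,
#' \hat\beta_{X(t-t_0)})}, referred to a chi-square distribution with 2
#' degrees of freedom.
#'
#' @param beta_pair Length-2 vector of intervention coefficients.
#' @param V_pair Their 2 x 2 covariance block (symmetric positive definite).
#' @param level Nominal test size.
#' @return A list with `chi2`, `p`, `reject`.
#' @examples
#' joint_intervention_test(c(1, 1), diag(2)) # chi2 = 2, p = exp(-1)
#' @export
joint_intervention_test <- function(beta_pair, V_pair, level = 0.05) {
  stopifnot(length(beta_pair) == 2, all(dim(V_pair) == c(2, 2)))
  ch <- tryCatch(chol(V_pair), error = function(e) NULL)
  if (is.null(ch)) stop("Covariance block is singular.", call. = FALSE)
  stat <- drop(crossprod(backsolve(ch, beta_pair, transpose = TRUE)))
  list(chi2 = stat,
       p = stats::pchisq(stat, df = 2, lower.tail = FALSE),
       reject = stat > stats::qchisq(1 - level, df = 2))
}
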