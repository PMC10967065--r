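#' Fit the Poisson log-linear GLM to a count series
#'
#' Maximum-likelihood Poisson regression ignoring the latent process; the
#' point estimates are consistent for the parameter-driven model, and this
#' fit seeds both covariance corrections. Fitting is iteratively reweighted
#' least squares via [stats::glm.fit()] with a tight convergence tolerance so
#' the score equations \eqn{\sum_t x_t (y_t - \hat\mu_t) = 0} hold to 1e-8.
#'
#' @param data A [count_series] (or data frame with `y`, design columns and
#'   optional `offset`).
#' @param max_iter Maximum IRLS iterations.
#' @return An object of class `pd_glm`: list with `beta_hat`, `mu_hat`
#'   (fitted means including the offset), `omega_I` (Fisher information
#'   \eqn{\sum_t x_t x_t^T \hat\mu_t}), `x`, `y`, `offset`, `converged`,
#'   `n_iter`.
#' @examples
#' d <- count_series(y = c(3, 3, 3, 3), x = matrix(1, 4, 1))
#' fit_poisson_glm(d)$beta_hat # log 3
#' @export
fit_poisson_glm <- function(data, max_iter = 100) {
  data <- as_count_series(data)
  y <- data$y
  off <- data$offset
  x <- as.matrix(data[setdiff(names(data), c("y", "offset"))])
  n <- nrow(x)
  p <- ncol(x)
  if (qr(x)$rank < p) {
    stop("Design matrix is rank deficient.", call. = FALSE)
  }
  if (all(y == 0)) {
    stop("All counts are zero: Poisson log-likelihood has no maximum.",
         call. = FALSE)
  }
  start <- c(log(mean(y) + 0.5) - mean(off), rep(0, p - 1))
  fit <- stats::glm.fit(
    x = x, y = y, offset = off, family = stats::poisson(),
    start = start,
    control = stats::glm.control(epsilon = 1e-12, maxit = max_iter)
  )
  beta <- fit$coefficients
  mu <- as.numeric(fit$fitted.values)
  score <- drop(crossprod(x, y - mu))
  if (!fit$converged || max(abs(score)) > 1e-8 * max(1, sum(y))) {
    stop("Poisson IRLS did not converge (max |score| = ",
         format(max(abs(score))), " after ", fit$iter, " iterations).",
         call. = FALSE)
  }
  structure(
    list(
      beta_hat = beta,
      mu_hat = mu,
      omega_I = crossprod(x, x * mu),
      x = x, y = y, offset = off,
      converged = fit$converged,
      n_iter = fit$iter
    ),
    class = "pd_glm"
  )
}

#' Naive GLM covariance of the coefficients
#'
#' The inverse Fisher information \eqn{\hat\Omega_{I,n}^{-1}}: the asymptotic
#' covariance reported by a standard Poisson GLM, valid only when the latent
#' process is absent.
#'
#' @param fit A `pd_glm` fit.
#' @return Symmetric positive-definite p x p matrix.
#' @export
naive_covariance <- function(fit) {
  stopifnot(inherits(fit, "pd_glm"))
  oi <- fit$omega_I
  rc <- tryCatch(chol(oi), error = function(e) NULL)
  if (is.null(rc)) {
    dg <- qr(oi)
    bad <- colnames(fit$x)[dg$pivot[seq(dg$rank + 1, ncol(oi))]]
    stop("Information matrix is singular; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  v <- chol2inv(rc)
  dimnames(v) <- dimnames(oi)
  (v + t(v)) / 2
}

#' @export
print.pd_glm <- function(x, ...) {
  cat("Poisson GLM fit (parameter-driven count series)\n")
  cat("  n =", length(x$y), " p =", length(x$beta_hat),
      " iterations =", x$n_iter, "\n")
  print(x$beta_hat)
  invisible(x)
}

#' Tidy a Poisson GLM fit
#'
#' Coefficient table with naive (uncorrected) standard errors; use
#' [ub_correct()] / [msrc_correct()] and their `tidy()` methods for
#' autocorrelation-robust inference.
#'
#' @param x A `pd_glm` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.pd_glm <- function(x, ...) {
  se <- sqrt(diag(naive_covariance(x)))
  z <- x$beta_hat / se
  tibble::tibble(
    term = colnames(x$x),
    estimate = unname(x$beta_hat),
    std.error = unname(se),
    statistic = unname(z),
    p.value = 2 * stats::pnorm(-abs(unname(z)))
  )
}

#' Glance at a Poisson GLM fit
#'
#' @param x A `pd_glm` object.
#' @param ... Unused.
#' @return One-row tibble with `n`, `p`, `deviance`, `converged`, `n_iter`.
#' @export
glance.pd_glm <- function(x, ...) {
  mu <- x$mu_hat
  y <- x$y
  dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  tibble::tibble(
    n = length(y), p = length(x$beta_hat),
    deviance = dev, converged = x$converged, n_iter = x$n_iter
  )
}
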