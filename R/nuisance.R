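# Moment estimators of the latent-process nuisance parameters, bias-adjusted
# by the current asymptotic covariance G of the regression coefficients.
# Exponents x_t^T G x_t are capped: |2q| > 50 signals a divergent fixed point.

.quad_form_diag <- function(x, G) {
  rowSums((x %*% G) * x)
}

.check_exponents <- function(q) {
  if (max(abs(2 * q)) > 50) {
    stop("Bias-correction exponent |2 x'Gx| > 50: corrected covariance has ",
         "diverged.", call. = FALSE)
  }
  invisible(q)
}

#' Unbiased-corrected moment estimator of the w-scale variance
#'
#' Moment estimator of \eqn{\sigma_w^2} with a bias adjustment for the
#' estimation error in \eqn{\hat\beta}; with `G = 0` it reduces exactly to
#' the classical estimator \eqn{\sum\{(Y_t-\hat\mu_t)^2 - \hat\mu_t\} /
#' \sum \hat\mu_t^2}. The result is floored at 1e-8 (attribute `floored`
#' records when the raw value was below the floor — expected under no
#' overdispersion).
#'
#' @param y Counts.
#' @param mu_hat Fitted means.
#' @param x Design matrix.
#' @param G Current p x p asymptotic covariance of the coefficients.
#' @param floor Lower bound for the returned variance.
#' @return Scalar estimate with attribute `floored`.
#' @export
estimate_sigma2_w <- function(y, mu_hat, x, G, floor = 1e-8) {
  x <- as.matrix(x)
  q <- .check_exponents(.quad_form_diag(x, G))
  adj <- mu_hat^2 * exp(-2 * q) * (exp(2 * q) - 2 * exp(q / 2) + 1)
  num <- sum((y - mu_hat)^2 + adj - mu_hat)
  den <- sum(mu_hat^2 * exp(-2 * q))
  s2 <- num / den
  flo <- s2 < floor
  structure(max(s2, floor), floored = flo)
}

#' Unbiased-corrected moment estimator of the w-scale autocorrelation
#'
#' Lag-h moment estimator of \eqn{\rho_w(h)} with the bias adjustment
#' involving \eqn{g_{t,h} = \exp\{-(x_t + x_{t+h})^T G (x_t + x_{t+h})/2\}};
#' with `G = 0` it reduces to the classical cross-moment ratio. Clamped to
#' (-0.999, 0.999).
#'
#' @inheritParams estimate_sigma2_w
#' @param sigma2_w w-scale variance estimate (> 0).
#' @param h Lag, `1 <= h <= n - 2`.
#' @return Scalar estimate with attribute `clamped`.
#' @export
estimate_rho_w <- function(y, mu_hat, x, G, sigma2_w, h) {
  x <- as.matrix(x)
  n <- length(y)
  stopifnot(h >= 1, h <= n - 2, sigma2_w > 0)
  q <- .check_exponents(.quad_form_diag(x, G))
  i1 <- seq_len(n - h)
  i2 <- i1 + h
  xs <- x[i1, , drop = FALSE] + x[i2, , drop = FALSE]
  g <- exp(-.check_exponents(.quad_form_diag(xs, G) / 2))
  mm <- mu_hat[i1] * mu_hat[i2]
  term <- (y[i1] - mu_hat[i1]) * (y[i2] - mu_hat[i2]) +
    mm * g * (1 - exp(q[i1] / 2) - exp(q[i2] / 2) + 1 / g)
  rho <- sum(term) / (sigma2_w * sum(mm * g))
  clamped <- abs(rho) >= 0.999
  structure(max(min(rho, 0.999), -0.999), clamped = clamped)
}

#' Approximate sampling variance of the lag-h autocorrelation estimator
#'
#' \deqn{\hat V\{\hat\rho_{w}(h)\} = \Big(\sum_t \hat\mu_t\hat\mu_{t+h}\Big)^{-2}
#'   \sum_t \hat\mu_t^2\hat\mu_{t+h}^2
#'   (1 + \hat\mu_t^{-1}\hat\sigma_w^{-2})(1 + \hat\mu_{t+h}^{-1}\hat\sigma_w^{-2}).}
#' For constant \eqn{\hat\mu} this is \eqn{(1 + 1/(\mu\sigma_w^2))^2/(n-h)},
#' decreasing in the series length.
#'
#' @param mu_hat Fitted means.
#' @param sigma2_w w-scale variance estimate (> 0).
#' @param h Lag (< n).
#' @return Positive scalar.
#' @export
rho_variance <- function(mu_hat, sigma2_w, h) {
  n <- length(mu_hat)
  stopifnot(h >= 1, h < n, sigma2_w > 0)
  i1 <- seq_len(n - h)
  i2 <- i1 + h
  mm <- mu_hat[i1] * mu_hat[i2]
  sum(mm^2 * (1 + 1 / (mu_hat[i1] * sigma2_w)) *
        (1 + 1 / (mu_hat[i2] * sigma2_w))) / sum(mm)^2
}

#' Latent-process contribution to the sandwich covariance
#'
#' The lag-truncated double sum
#' \deqn{\hat\Omega_{II,n} = \sum_{h=-L}^{L} \sum_t x_t x_{t+h}^T
#'   \hat\mu_t \hat\mu_{t+h}\, \hat\gamma_w(h),}
#' equal to the full double sum over all (t, s) pairs restricted to
#' |s - t| <= L.
#'
#' @param x Design matrix.
#' @param mu_hat Fitted means.
#' @param gamma_w Either a function `h -> autocovariance` (h >= 0) or a
#'   numeric vector of autocovariances at lags `0..L`.
#' @param L Truncation lag, `0 <= L <= n - 1`.
#' @return Symmetric p x p matrix.
#' @export
build_omega_II <- function(x, mu_hat, gamma_w, L) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(L >= 0, L <= n - 1)
  gv <- if (is.function(gamma_w)) vapply(0:L, gamma_w, 0) else gamma_w
  stopifnot(length(gv) >= L + 1)
  xmu <- x * mu_hat
  om <- gv[1] * crossprod(xmu)
  if (L >= 1) {
    for (h in seq_len(L)) {
      if (gv[h + 1] == 0) next
      a <- crossprod(xmu[seq_len(n - h), , drop = FALSE],
                     xmu[seq_len(n - h) + h, , drop = FALSE])
      om <- om + gv[h + 1] * (a + t(a))
    }
  }
  (om + t(om)) / 2
}
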