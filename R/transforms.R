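#' Latent-scale to observation-scale variance transform
#'
#' Under the parameter-driven Poisson model the log mean carries a latent
#' stationary Gaussian process \eqn{\alpha_t \sim N(-\sigma_\alpha^2/2,
#' \sigma_\alpha^2)}; the multiplicative noise is \eqn{w_t = \exp(\alpha_t)}
#' with \eqn{E[w_t] = 1}. Its variance on the observation (w) scale is
#' \deqn{\sigma_w^2 = \exp(\sigma_\alpha^2) - 1.}
#'
#' @param sigma2_alpha Non-negative variance of the latent Gaussian process.
#' @return The w-scale variance \eqn{\sigma_w^2 \ge 0}.
#' @examples
#' alpha_to_w_variance(0.5)
#' @export
alpha_to_w_variance <- function(sigma2_alpha) {
  stopifnot(is.numeric(sigma2_alpha))
  if (any(sigma2_alpha < 0)) {
    stop("`sigma2_alpha` must be non-negative.", call. = FALSE)
  }
  exp(sigma2_alpha) - 1
}

#' Observation-scale to latent-scale variance transform
#'
#' Inverse of [alpha_to_w_variance()]: \eqn{\sigma_\alpha^2 =
#' \log(1 + \sigma_w^2)}.
#'
#' @param sigma2_w Non-negative w-scale variance.
#' @return The latent-scale variance.
#' @export
w_to_alpha_variance <- function(sigma2_w) {
  stopifnot(is.numeric(sigma2_w))
  if (any(sigma2_w < 0)) stop("`sigma2_w` must be non-negative.", call. = FALSE)
  log1p(sigma2_w)
}

#' Latent-scale to observation-scale autocorrelation transform
#'
#' Maps the lag-h autocorrelation of the latent Gaussian process to the
#' autocorrelation of \eqn{w_t = \exp(\alpha_t)}:
#' \deqn{\rho_w(h) = \frac{\exp(\rho_\alpha(h)\,\sigma_\alpha^2) - 1}
#'                        {\exp(\sigma_\alpha^2) - 1}.}
#' The map fixes 0 and 1 and is strictly increasing in \eqn{\rho_\alpha(h)}.
#'
#' @param rho_alpha_h Latent-scale autocorrelation, in \eqn{[-1, 1]}.
#' @param sigma2_alpha Latent-scale variance (> 0; at exactly 0 the transform
#'   is degenerate and the limit value `rho_alpha_h` is returned with a
#'   message).
#' @return The w-scale autocorrelation.
#' @examples
#' alpha_to_w_rho(0.8, 0.5)
#' @export
alpha_to_w_rho <- function(rho_alpha_h, sigma2_alpha) {
  stopifnot(is.numeric(rho_alpha_h), is.numeric(sigma2_alpha),
            length(sigma2_alpha) == 1L)
  if (any(abs(rho_alpha_h) > 1)) {
    stop("`rho_alpha_h` must lie in [-1, 1].", call. = FALSE)
  }
  if (sigma2_alpha < 0) stop("`sigma2_alpha` must be >= 0.", call. = FALSE)
  if (sigma2_alpha == 0) {
    message("sigma2_alpha = 0: degenerate transform, returning the limit ",
            "value rho_alpha_h.")
    return(rho_alpha_h)
  }
  expm1(rho_alpha_h * sigma2_alpha) / expm1(sigma2_alpha)
}

#' Observation-scale to latent-scale autocorrelation transform
#'
#' Exact inverse of [alpha_to_w_rho()]:
#' \deqn{\rho_\alpha(h) = \log\{1 + \rho_w(h)(\exp(\sigma_\alpha^2) - 1)\} /
#'   \sigma_\alpha^2.}
#'
#' @param rho_w_h w-scale autocorrelation, inside the image of
#'   [alpha_to_w_rho()] for the given variance.
#' @param sigma2_alpha Latent-scale variance (> 0).
#' @return The latent-scale autocorrelation.
#' @export
w_to_alpha_rho <- function(rho_w_h, sigma2_alpha) {
  stopifnot(is.numeric(rho_w_h), is.numeric(sigma2_alpha),
            length(sigma2_alpha) == 1L)
  if (sigma2_alpha <= 0) stop("`sigma2_alpha` must be > 0.", call. = FALSE)
  arg <- 1 + rho_w_h * expm1(sigma2_alpha)
  if (any(arg <= 0)) {
    stop("Inadmissible `rho_w_h`: 1 + rho_w * (exp(sigma2_alpha) - 1) <= 0 ",
         "(w-scale autocorrelation too negative for this variance).",
         call. = FALSE)
  }
  log(arg) / sigma2_alpha
}

#' Marginal moments of the parameter-driven Poisson process
#'
#' Given regressor values and latent-process parameters, returns the marginal
#' mean, variance and lag-h autocorrelation of the counts:
#' \deqn{\mu_t = \exp(x_t^T\beta), \quad Var[Y_t] = \mu_t + \sigma_w^2\mu_t^2,}
#' \deqn{\rho_Y(h) = \rho_w(h) \Big/ \big[\{1 + (\sigma_w^2\mu_t)^{-1}\}^{1/2}
#'   \{1 + (\sigma_w^2\mu_{t+h})^{-1}\}^{1/2}\big].}
#'
#' @param x_t Numeric regressor vector at time t (or a precomputed scalar
#'   linear predictor via `mu_t`).
#' @param beta Coefficient vector matching `x_t`.
#' @param sigma2_alpha,rho_alpha Latent AR(1) parameters.
#' @param h Non-negative integer lag.
#' @param x_th Regressors at time t + h; defaults to `x_t` (stationary mean).
#' @return A tibble with columns `mu_t`, `var_t`, `rho_Y`.
#' @examples
#' marginal_moments(x_t = 1, beta = log(3), sigma2_alpha = 0.5,
#'                  rho_alpha = 0.8, h = 1)
#' @export
marginal_moments <- function(x_t, beta, sigma2_alpha, rho_alpha, h = 1,
                             x_th = x_t) {
  stopifnot(length(x_t) == length(beta), h >= 0)
  mu_t <- exp(sum(x_t * beta))
  mu_th <- exp(sum(x_th * beta))
  s2w <- alpha_to_w_variance(sigma2_alpha)
  var_t <- mu_t + s2w * mu_t^2
  if (s2w == 0 && h > 0) {
    rho_y <- 0
  } else if (h == 0) {
    rho_y <- 1
  } else {
    rho_w <- alpha_to_w_rho(rho_alpha^h, sigma2_alpha)
    rho_y <- rho_w / (sqrt(1 + 1 / (s2w * mu_t)) * sqrt(1 + 1 / (s2w * mu_th)))
  }
  tibble::tibble(mu_t = mu_t, var_t = var_t, rho_Y = rho_y)
}
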