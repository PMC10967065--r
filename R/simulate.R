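#' Simulate a stationary latent Gaussian AR(1) process
#'
#' Draws \eqn{\alpha_1 \sim N(\mu_\alpha, \sigma_\alpha^2)} from the
#' stationary law (no burn-in) and recurses
#' \eqn{\alpha_t = \mu_\alpha + \rho_\alpha(\alpha_{t-1} - \mu_\alpha) +
#' \epsilon_t} with \eqn{\epsilon_t \sim N(0, \sigma_\alpha^2(1 -
#' \rho_\alpha^2))}. The mean is pinned at \eqn{-\sigma_\alpha^2/2} so that
#' \eqn{E[\exp(\alpha_t)] = 1} (identifiability of the Poisson regression
#' intercept).
#'
#' @param n Series length (>= 1).
#' @param sigma2_alpha Latent variance (>= 0; 0 gives the degenerate constant
#'   process at its mean, 0).
#' @param rho_alpha Lag-1 autocorrelation, |rho_alpha| < 1.
#' @param seed Optional integer seed; when supplied the draw is reproducible.
#' @return Numeric vector of length `n`.
#' @examples
#' a <- simulate_latent_ar1(10, 0.5, 0.8, seed = 1)
#' @export
simulate_latent_ar1 <- function(n, sigma2_alpha, rho_alpha, seed = NULL) {
  stopifnot(n >= 1, sigma2_alpha >= 0, abs(rho_alpha) < 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  mu_a <- -sigma2_alpha / 2
  if (sigma2_alpha == 0) return(rep(0, n))
  innov_sd <- sqrt(sigma2_alpha * (1 - rho_alpha^2))
  eps <- stats::rnorm(n, 0, innov_sd)
  alpha <- numeric(n)
  alpha[1] <- stats::rnorm(1, mu_a, sqrt(sigma2_alpha))
  if (n > 1) {
    # centred recursion; filter() is the vectorised AR(1) pass
    centred <- stats::filter(eps[-1], rho_alpha, method = "recursive",
                             init = alpha[1] - mu_a)
    alpha[-1] <- mu_a + as.numeric(centred)
  }
  alpha
}

#' Simulate counts from the parameter-driven Poisson model
#'
#' Given a design matrix, coefficients, a latent-process path and an optional
#' log-exposure offset, draws \eqn{Y_t \mid \alpha_t \sim
#' \mathrm{Poisson}(\exp(\mathrm{offset}_t + \alpha_t + x_t^T\beta))}.
#'
#' @param x Design matrix (n x p) or data frame of regressors.
#' @param beta Coefficient vector of length p.
#' @param alpha Latent-process vector of length n (use zeros for a plain GLM
#'   data-generating process).
#' @param offset Optional log-exposure vector (default 0).
#' @param seed Optional integer seed.
#' @return A [count_series] tibble with columns `y`, the regressors and
#'   `offset`.
#' @export
simulate_counts <- function(x, beta, alpha, offset = NULL, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(beta) == ncol(x), length(alpha) == n)
  if (is.null(offset)) offset <- rep(0, n)
  stopifnot(length(offset) == n, all(is.finite(offset)))
  eta <- offset + alpha + drop(x %*% beta)
  if (any(eta > 700)) {
    stop("Poisson mean overflow: exponent > 700 at t = ",
         which(eta > 700)[1], call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  y <- stats::rpois(n, exp(eta))
  count_series(y = y, x = x, offset = offset)
}

#' Construct a count-series table
#'
#' The container every estimator in the package consumes: a tibble with a
#' count column `y`, the design columns (first column conventionally an
#' all-ones intercept) and a log-exposure `offset` column (zero when absent).
#'
#' @param y Non-negative integer counts.
#' @param x Design matrix or data frame; column names are kept, unnamed
#'   columns become `x1..xp`.
#' @param offset Optional log-exposure vector.
#' @return A tibble of class `count_series`.
#' @export
count_series <- function(y, x, offset = NULL) {
  x <- as.matrix(x)
  n <- length(y)
  stopifnot(nrow(x) == n)
  if (any(y < 0) || any(y != round(y))) {
    stop("`y` must be non-negative integers.", call. = FALSE)
  }
  if (is.null(offset)) offset <- rep(0, n)
  stopifnot(length(offset) == n, all(is.finite(offset)))
  nm <- colnames(x)
  if (is.null(nm) || any(nm == "")) nm <- paste0("x", seq_len(ncol(x)))
  colnames(x) <- nm
  out <- tibble::as_tibble(as.data.frame(x))
  out <- tibble::add_column(out, y = as.integer(round(y)), .before = 1)
  out$offset <- offset
  class(out) <- c("count_series", class(out))
  out
}

#' Coerce a data frame to a count series
#'
#' Any data frame with a `y` column, optional `offset` column and remaining
#' columns forming the design is accepted.
#'
#' @param data A data frame.
#' @return A `count_series` tibble.
#' @export
as_count_series <- function(data) {
  stopifnot(is.data.frame(data), "y" %in% names(data))
  off <- if ("offset" %in% names(data)) data$offset else NULL
  xcols <- setdiff(names(data), c("y", "offset"))
  count_series(y = data$y, x = as.matrix(data[xcols]), offset = off)
}

#' Read / write a count series as delimited text
#'
#' Plain CSV with a header: column `y`, then the design columns, then
#' `offset`. `read_count_series()` inverts `write_count_series()` exactly.
#'
#' @param data A `count_series` (or coercible data frame).
#' @param file Path to a CSV file.
#' @return `read_count_series()` returns a `count_series` tibble;
#'   `write_count_series()` returns `data` invisibly.
#' @export
write_count_series <- function(data, file) {
  data <- as_count_series(data)
  readr::write_csv(as.data.frame(data), file)
  invisible(data)
}

#' @rdname write_count_series
#' @export
read_count_series <- function(file) {
  as_count_series(readr::read_csv(file, show_col_types = FALSE))
}

#' Interrupted time-series design matrix
#'
#' Builds the standard segmented-regression design
#' \eqn{x_t^T = (1, t, X_t, X_t (t - t_0))} with intervention indicator
#' \eqn{X_t = 1} for \eqn{t > t_0} (the change point itself counts as
#' pre-intervention). With `scale_time = TRUE` the time columns are divided
#' by n, so coefficients are per study length rather than per time step; the
#' simulation harness uses that scaling to keep expected counts in a
#' realistic range.
#'
#' @param n Series length.
#' @param t0 Intervention start index, `1 <= t0 < n`; default `n %/% 2`.
#' @param scale_time Divide the trend and interaction columns by n?
#' @return A tibble with columns `intercept`, `t`, `X`, `Xt` and attributes
#'   `n`, `t0`.
#' @examples
#' build_its_design(4, 2)
#' @export
build_its_design <- function(n, t0 = n %/% 2, scale_time = FALSE) {
  stopifnot(n >= 2, t0 >= 1, t0 < n)
  t <- seq_len(n)
  X <- as.numeric(t > t0)
  denom <- if (scale_time) n else 1
  Xt <- X * (t - t0) / denom # from raw t, before t itself is scaled
  out <- tibble::tibble(intercept = rep(1, n), t = t / denom, X = X, Xt = Xt)
  attr(out, "n") <- n
  attr(out, "t0") <- t0
  attr(out, "scaled") <- scale_time
  out
}
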