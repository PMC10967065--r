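test_that("intercept-only fit mean-matches and gives the 1/sum(mu) variance", {
  d <- count_series(c(3, 3, 3, 3), matrix(1, 4, 1))
  fit <- fit_poisson_glm(d)
  expect_equal(unname(fit$beta_hat), log(3), tolerance = 1e-10)
  expect_equal(unname(fit$omega_I[1, 1]), 12, tolerance = 1e-8)
  expect_equal(unname(naive_covariance(fit)[1, 1]), 1 / 12, tolerance = 1e-8)
})

test_that("fit solves the score equations, checked against a likelihood grid", {
  x <- cbind(1, 1:4)
  d <- count_series(1:4, x)
  fit <- fit_poisson_glm(d)
  expect_lt(max(abs(crossprod(x, d$y - fit$mu_hat))), 1e-8 * sum(d$y))
  # brute-force oracle: profile the log-likelihood on a grid around the MLE
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * (1:4)
    sum((1:4) * eta - exp(eta))
  }
  coarse <- expand.grid(b0 = seq(-2, 1, by = 1e-2), b1 = seq(0, 1, by = 1e-2))
  best <- coarse[which.max(mapply(loglik, coarse$b0, coarse$b1)), ]
  fine <- expand.grid(b0 = best$b0 + seq(-2e-2, 2e-2, by = 1e-4),
                      b1 = best$b1 + seq(-2e-2, 2e-2, by = 1e-4))
  best <- fine[which.max(mapply(loglik, fine$b0, fine$b1)), ]
  expect_lt(abs(unname(fit$beta_hat[1]) - best$b0), 1e-4 + 1e-8)
  expect_lt(abs(unname(fit$beta_hat[2]) - best$b1), 1e-4 + 1e-8)
})

test_that("a constant log-exposure offset shifts only the intercept", {
  d <- its_data(60, 0.3, 0.4, seed = 2)
  fit0 <- fit_poisson_glm(d)
  d_off <- d
  d_off$offset <- rep(0.7, 60)
  fit1 <- fit_poisson_glm(d_off)
  expect_equal(fit1$beta_hat[1], fit0$beta_hat[1] - 0.7, tolerance = 1e-7)
  expect_equal(fit1$beta_hat[-1], fit0$beta_hat[-1], tolerance = 1e-7)
})

test_that("degenerate inputs error informatively", {
  expect_error(fit_poisson_glm(count_series(rep(0, 10), matrix(1, 10, 1))),
               "zero")
  x <- cbind(1, 1:6, 2 * (1:6))
  expect_error(fit_poisson_glm(count_series(1:6, x)), "rank")
})

test_that("naive covariance inverts the information matrix", {
  fit <- its_fit(n = 80, seed = 4)
  v <- naive_covariance(fit)
  expect_equal(v %*% fit$omega_I, diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(v, t(v))
  # 2x2 case against the closed-form cofactor inverse
  d <- count_series(c(2, 5, 3, 7), cbind(1, c(0, 1, 0, 1)))
  f2 <- fit_poisson_glm(d)
  oi <- f2$omega_I
  cof <- matrix(c(oi[2, 2], -oi[1, 2], -oi[2, 1], oi[1, 1]), 2) /
    (oi[1, 1] * oi[2, 2] - oi[1, 2] * oi[2, 1])
  expect_equal(naive_covariance(f2), cof, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("without a latent process the naive covariance is correct", {
  # correctly specified GLM: Monte Carlo variance of beta-hat matches the
  # inverse information computed at the truth
  n <- 120
  X <- as.matrix(build_its_design(n, 60, scale_time = TRUE))
  beta <- c(1, 1, 0, 0)
  mu <- exp(drop(X %*% beta))
  v_theory <- solve(crossprod(X, X * mu))
  B <- 800
  est <- matrix(NA_real_, B, 4)
  for (r in seq_len(B)) {
    d <- simulate_counts(X, beta, alpha = rep(0, n), seed = 5000 + r)
    est[r, ] <- fit_poisson_glm(d)$beta_hat
  }
  v_mc <- diag(stats::cov(est))
  expect_lt(max(abs(v_mc / diag(v_theory) - 1)), 0.15)
})

test_that("tidy and glance summarise the fit", {
  fit <- its_fit(n = 100, seed = 8)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$term, c("intercept", "t", "X", "Xt"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n, 100)
})
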