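test_that("without overdispersion the correction collapses to the naive GLM", {
  # constant counts fit exactly: the variance estimator floors, gamma is
  # identically zero and the sandwich equals the inverse information
  d <- count_series(rep(3, 50), matrix(1, 50, 1))
  fit <- fit_poisson_glm(d)
  ub <- ub_correct(fit)
  expect_true(ub$nuisance$floored)
  expect_identical(ub$G_n, naive_covariance(fit))
  expect_equal(ub$omega_II, matrix(0, 1, 1))
  ms <- msrc_correct(fit)
  expect_identical(ms$G_n, naive_covariance(fit))
  expect_true(ms$selection$fallback_used)
})

test_that("the correction never shrinks the variance for positive dependence", {
  for (seed in c(3, 14, 25)) {
    fit <- its_fit(n = 200, sigma2_alpha = 0.5, rho_alpha = 0.6, seed = seed)
    ub <- suppressWarnings(ub_correct(fit))
    if (ub$rho1_used >= 0) {
      expect_true(all(diag(ub$G_n) >= diag(ub$omega_I_inv) - 1e-10))
    }
    expect_equal(ub$G_n, t(ub$G_n))
    expect_equal(ub$method, "UB")
  }
})

test_that("MSRC standard errors dominate UB when it selects a larger rho", {
  for (seed in c(5, 16, 27, 38)) {
    fit <- its_fit(n = 300, sigma2_alpha = 0.5, rho_alpha = 0.8, seed = seed)
    ub <- suppressWarnings(ub_correct(fit))
    ms <- suppressWarnings(msrc_correct(fit))
    if (ms$rho1_used >= ub$rho1_used && ub$rho1_used >= 0) {
      expect_true(all(diag(ms$G_n) >= diag(ub$G_n) - 1e-10))
    }
  }
})

test_that("restricted to lag 1 the MSRC pipeline reproduces UB exactly", {
  for (seed in c(6, 21)) {
    fit <- its_fit(n = 150, sigma2_alpha = 0.5, rho_alpha = 0.6, seed = seed)
    ub <- suppressWarnings(ub_correct(fit, H_max = 1))
    ms <- suppressWarnings(msrc_correct(fit, H_max = 1))
    expect_equal(ms$G_n, ub$G_n, tolerance = 1e-12)
    expect_equal(ms$rho1_used, ub$rho1_used)
  }
})

test_that("raising the lag ceiling is conservative replicate by replicate", {
  # more candidate lags can only raise the selected maximum, hence the SEs
  n <- 180
  X <- as.matrix(build_its_design(n, 90, scale_time = TRUE))
  for (r in 1:40) {
    alpha <- simulate_latent_ar1(n, 0.5, 0.8, seed = 9000 + 2 * r)
    d <- simulate_counts(X, c(1, 1, 0, 0), alpha, seed = 9001 + 2 * r)
    fit <- fit_poisson_glm(d)
    m5 <- suppressWarnings(msrc_correct(fit, H_max = 5))
    m7 <- suppressWarnings(msrc_correct(fit, H_max = 7))
    expect_gte(m7$rho1_used, m5$rho1_used - 1e-12)
    expect_true(all(diag(m7$G_n) >= diag(m5$G_n) - 1e-10))
  }
})

test_that("the empirical-gamma variant truncates at H_max", {
  fit <- its_fit(n = 200, sigma2_alpha = 0.5, rho_alpha = 0.6, seed = 30)
  ub <- suppressWarnings(ub_correct(fit, gamma_structure = "empirical"))
  expect_equal(ub$L, 5L)
  expect_equal(ub$G_n, t(ub$G_n))
})

test_that("nuisance recovery is unbiased at moderate autocorrelation", {
  # latent-scale means of (sigma2, rho(1)) near truth at n = 500; the
  # order-1 estimator's downward bias only sets in at rho >= 0.6
  n <- 500
  X <- as.matrix(build_its_design(n, 250, scale_time = TRUE))
  for (truth in list(c(0.5, 0.2), c(1.0, 0.4))) {
    B <- 250
    s2a <- ra <- rep(NA_real_, B)
    for (r in seq_len(B)) {
      alpha <- simulate_latent_ar1(n, truth[1], truth[2], seed = 3000 + 2 * r)
      d <- simulate_counts(X, c(1, 1, 0, 0), alpha, seed = 3001 + 2 * r)
      ub <- suppressWarnings(ub_correct(fit_poisson_glm(d)))
      s2a[r] <- log1p(ub$nuisance$sigma2_w)
      ra[r] <- w_to_alpha_rho(max(ub$rho1_used, 0), log1p(ub$nuisance$sigma2_w))
    }
    expect_lt(abs(mean(s2a) - truth[1]), 0.03 + 3 * sd(s2a) / sqrt(B))
    expect_lt(abs(mean(ra) - truth[2]), 0.03 + 3 * sd(ra) / sqrt(B))
  }
})

test_that("corrected-covariance summaries expose the nuisance estimates", {
  fit <- its_fit(n = 200, sigma2_alpha = 0.5, rho_alpha = 0.6, seed = 44)
  ms <- suppressWarnings(msrc_correct(fit))
  td <- tidy(ms)
  expect_equal(td$estimate, unname(fit$beta_hat))
  expect_equal(td$std.error, unname(sqrt(diag(ms$G_n))))
  gl <- glance(ms)
  expect_equal(gl$method, "MSRC")
  expect_equal(gl$sigma2_alpha, log1p(gl$sigma2_w))
})
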