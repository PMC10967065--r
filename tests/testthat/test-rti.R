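make_cov <- function(n_days = 400, t0 = 100, seed = 50) {
  synthesize_rti_data(n_days = max(n_days, 730), t0_index = t0,
                      sigma2_alpha = 0, rho_alpha = 0, seed = seed)$covariates
}

test_that("the daily design has the documented column structure", {
  cov <- make_cov()
  des <- build_rti_design(cov, k = 2)
  nm <- names(des)
  expect_equal(sum(grepl("^(sin|cos)", nm)), 4) # k = 2 harmonic pairs
  expect_equal(sum(grepl("^dow_", nm)), 6)
  expect_equal(sum(grepl("^holiday_", nm)), 2)
  expect_equal(sum(grepl("^precip_", nm)), 2)
  expect_equal(sum(grepl("^temp_ns", nm)), 3)
  expect_equal(sum(grepl("^X_ns", nm)), 5)
  expect_equal(des$offset, log(cov$pop_car_product))
  # intervention interactions vanish pre-intervention
  pre <- cov$intervention == 0
  expect_true(all(as.matrix(des[pre, grepl("^X_ns|^X$", nm)]) == 0))
})

test_that("harmonic columns are periodic in the stated period", {
  cov <- make_cov(n_days = 740)
  des <- build_rti_design(cov, k = 2, period = 7) # integer period to compare
  h <- as.matrix(des[grepl("^(sin|cos)", names(des))])
  expect_equal(h[1:20, ], h[1:20 + 7, ], tolerance = 1e-12)
})

test_that("design construction validates categories and exposure", {
  cov <- make_cov()
  bad <- cov
  bad$holiday <- as.character(bad$holiday)
  bad$holiday[5] <- "solstice"
  expect_error(build_rti_design(bad), "solstice")
  bad2 <- cov
  bad2$pop_car_product[3] <- 0
  expect_error(build_rti_design(bad2), "positive")
  expect_equal(as.character(precip_category(c(0, 1, 2.5, 3))),
               c("none", "mild", "mild", "severe"))
})

test_that("without a latent process the fitted model leaves white residuals", {
  syn <- synthesize_rti_data(n_days = 1096, sigma2_alpha = 0, rho_alpha = 0,
                             seed = 61)
  fit <- fit_poisson_glm(syn$series)
  resid <- (fit$y - fit$mu_hat) / sqrt(fit$mu_hat)
  pac <- stats::pacf(resid, lag.max = 10, plot = FALSE)$acf
  expect_lt(max(abs(pac)), 0.1) # ~ 3.3 / sqrt(n) under whiteness
})

test_that("excess risk is zero with null intervention coefficients", {
  syn <- synthesize_rti_data(n_days = 900, sigma2_alpha = 0, rho_alpha = 0,
                             er_step = 0, seed = 62)
  fit <- fit_poisson_glm(syn$series)
  # force the intervention block to zero to isolate the transform
  fit$beta_hat[attr(syn$design, "intervention_cols")] <- 0
  p <- length(fit$beta_hat)
  er <- excess_risk_curve(fit, matrix(0, p, p, dimnames = list(colnames(fit$x), colnames(fit$x))),
                          syn$design, times = c(300, 600))
  expect_equal(er$er_pct, c(0, 0))
  expect_equal(er$ci_lo, er$er_pct) # V = 0 collapses the interval
  expect_equal(er$ci_hi, er$er_pct)
})

test_that("no extrapolation beyond the time-spline boundary", {
  syn <- synthesize_rti_data(n_days = 800, seed = 63)
  fit <- fit_poisson_glm(syn$series)
  expect_error(
    excess_risk_curve(fit, naive_covariance(fit), syn$design, times = 900),
    "boundary")
})

test_that("the delta-method interval matches a parametric bootstrap", {
  skip_if_not_installed("MASS")
  syn <- synthesize_rti_data(n_days = 1096, sigma2_alpha = 0.2,
                             rho_alpha = 0.4, er_step = -0.4, seed = 64)
  fit <- fit_poisson_glm(syn$series)
  ms <- suppressWarnings(msrc_correct(fit))
  tt <- 700
  er <- excess_risk_curve(fit, ms, syn$design, tt)
  icols <- attr(syn$design, "intervention_cols")
  idx <- match(icols, colnames(fit$x))
  set.seed(99)
  draws <- MASS::mvrnorm(1e6, fit$beta_hat[idx], ms$G_n[idx, idx])
  row <- cbind(1, pdcount:::.time_basis_at(syn$design, tt))
  eta <- drop(draws %*% t(row))
  boot_ci <- 100 * expm1(stats::quantile(eta, c(0.025, 0.975)))
  expect_equal(unname(boot_ci[1]), er$ci_lo, tolerance = 0.01)
  expect_equal(unname(boot_ci[2]), er$ci_hi, tolerance = 0.01)
})

test_that("all three methods share the point estimate, with ordered intervals", {
  syn <- synthesize_rti_data(n_days = 1096, sigma2_alpha = 0.3,
                             rho_alpha = 0.6, seed = 65)
  fit <- fit_poisson_glm(syn$series)
  nv <- naive_covariance(fit)
  ub <- suppressWarnings(ub_correct(fit))
  ms <- suppressWarnings(msrc_correct(fit))
  times <- c(400, 700, 1000)
  e_nv <- excess_risk_curve(fit, nv, syn$design, times)
  e_ub <- excess_risk_curve(fit, ub, syn$design, times)
  e_ms <- excess_risk_curve(fit, ms, syn$design, times)
  expect_equal(e_ub$er_pct, e_nv$er_pct)
  expect_equal(e_ms$er_pct, e_nv$er_pct)
  if (ms$rho1_used >= ub$rho1_used && ub$rho1_used >= 0) {
    expect_true(all(e_nv$se_log <= e_ub$se_log + 1e-12))
    expect_true(all(e_ub$se_log <= e_ms$se_log + 1e-12))
  }
  p <- autoplot(dplyr::bind_rows(e_nv, e_ub, e_ms))
  expect_s3_class(p, "ggplot")
})

test_that("the generator runs a seven-year series end to end quickly", {
  elapsed <- system.time({
    syn <- synthesize_rti_data(n_days = 2557, seed = 66)
    fit <- fit_poisson_glm(syn$series)
    ms <- suppressWarnings(msrc_correct(fit))
    er <- excess_risk_curve(fit, ms, syn$design, c(1000, 2000))
  })[["elapsed"]]
  expect_lt(elapsed, 60)
  expect_true(all(er$ci_lo <= er$er_pct & er$er_pct <= er$ci_hi))
  expect_true(all(er$er_pct > -100))
})
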