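# Synthetic daily road-traffic-injury-style data. The real motivating series
# (7 years of daily ambulance call-outs) is not public; this generator
# emulates its structure — harmonic seasonality, day-of-week and holiday
# effects, precipitation and temperature covariates, slowly growing
# exposure, a latent AR(1) process in the log mean, and a mid-series
# intervention — with a known true excess-risk curve for recovery tests.

.synthetic_holidays <- function(dates) {
  m <- as.integer(format(dates, "%m"))
  d <- as.integer(format(dates, "%d"))
  # synthetic calendar: a 7-day early-February festival stands in for the
  # lunar Spring Festival; fixed-date public holidays otherwise
  spring <- m == 2 & d <= 7
  other <- (m == 1 & d == 1) | (m == 5 & d <= 3) | (m == 10 & d <= 7)
  factor(ifelse(spring, "spring_festival", ifelse(other, "other", "none")),
         levels = .holiday_levels)
}

#' Synthesize a daily count series with a known intervention effect
#'
#' Generates a daily covariate table (calendar-true day of week, synthetic
#' holiday calendar, sinusoidal temperature with noise, seasonally varying
#' precipitation categories, exponentially growing exposure) and counts from
#' the parameter-driven Poisson model with latent AR(1) autocorrelation and
#' a step intervention effect of known excess risk. Because the generating
#' coefficients live in the span of [build_rti_design()], the fitted model
#' is correctly specified apart from the latent process.
#'
#' @param n_days Number of days (>= 730).
#' @param start_date First day.
#' @param t0_index Intervention start index; default `n_days %/% 5`,
#'   mirroring an intervention early in a multi-year surveillance series.
#'   (With the full-period interaction spline, a very late `t0` can leave
#'   too few spline knots post-intervention for the interaction columns to
#'   be identifiable.)
#' @param sigma2_alpha,rho_alpha Latent AR(1) parameters.
#' @param er_step True post-intervention excess risk as a fraction (default
#'   -0.4, i.e. a 40% reduction); the true curve is this step at all
#'   post-intervention times.
#' @param beta_intervention Optional length `1 + int_df` coefficient vector
#'   for (X, X * ns(t)) overriding `er_step`, for a time-varying truth.
#' @param mean_daily_count Target pre-intervention mean daily count.
#' @param int_df Spline df of the intervention interaction.
#' @param seed Optional integer seed (covariates, latent process and counts
#'   draw from seed, seed + 1, seed + 2).
#' @return A list: `covariates` (tibble), `series` (fittable
#'   [count_series] containing the design columns), `design` (the design
#'   tibble with basis attributes), `beta_true`, `t0_index`, and
#'   `true_er(times)` — a function returning the true excess-risk (%) curve.
#' @export
synthesize_rti_data <- function(n_days = 1461,
                                start_date = as.Date("2010-01-01"),
                                t0_index = n_days %/% 5,
                                sigma2_alpha = 0.3, rho_alpha = 0.6,
                                er_step = -0.4, beta_intervention = NULL,
                                mean_daily_count = 30, int_df = 5,
                                seed = NULL) {
  stopifnot(n_days >= 730, t0_index >= 1, t0_index < n_days)
  if (!is.null(seed)) set.seed(as.integer(seed))
  dates <- seq(as.Date(start_date), by = "day", length.out = n_days)
  t <- seq_len(n_days)
  doy <- 2 * pi * (t %% 365.25) / 365.25
  temp <- 23 + 7 * sin(doy - 1.9) + stats::rnorm(n_days, 0, 1.8)
  p_wet <- 0.12 + 0.28 * (sin(doy - 1.6) + 1) / 2 # wetter in summer
  wet <- stats::runif(n_days) < p_wet
  severe <- wet & stats::runif(n_days) < 0.25
  precip <- factor(ifelse(!wet, "none", ifelse(severe, "severe", "mild")),
                   levels = .precip_levels)
  dow <- factor(.dow_levels[as.integer(format(dates, "%u"))],
                levels = .dow_levels)
  covariates <- tibble::tibble(
    date = dates,
    pop_car_product = 1e6 * exp(0.06 * t / 365.25),
    dow = dow,
    holiday = .synthetic_holidays(dates),
    precip_cat = precip,
    temp = temp,
    intervention = as.numeric(t > t0_index)
  )
  design <- build_rti_design(covariates, int_df = int_df)
  xnames <- setdiff(names(design), "offset")
  k_harm <- sum(grepl("^(sin|cos)", xnames))

  if (is.null(beta_intervention)) {
    beta_intervention <- c(log1p(er_step), rep(0, int_df))
  }
  stopifnot(length(beta_intervention) == 1 + int_df)
  beta <- c(
    intercept = 0,
    stats::setNames(c(0.10, 0.06, 0.03, 0.02)[seq_len(k_harm)],
                    xnames[1 + seq_len(k_harm)]),
    dow_Tue = 0.01, dow_Wed = 0.00, dow_Thu = 0.02, dow_Fri = 0.05,
    dow_Sat = 0.12, dow_Sun = 0.08,
    holiday_spring_festival = -0.25, holiday_other = 0.08,
    precip_mild = -0.05, precip_severe = -0.15,
    temp_ns1 = 0.05, temp_ns2 = 0.08, temp_ns3 = 0.06,
    t = -0.05,
    stats::setNames(beta_intervention, c("X", paste0("X_ns", seq_len(int_df))))
  )
  beta <- beta[xnames] # align with design column order
  xmat <- as.matrix(design[xnames])
  rest <- drop(xmat[, -1, drop = FALSE] %*% beta[-1]) + design$offset
  beta[1] <- log(mean_daily_count) - log(mean(exp(rest[t <= t0_index])))

  alpha <- simulate_latent_ar1(n_days, sigma2_alpha, rho_alpha,
                               seed = if (is.null(seed)) NULL else seed + 1L)
  series <- simulate_counts(xmat, beta, alpha, offset = design$offset,
                            seed = if (is.null(seed)) NULL else seed + 2L)
  b_int <- beta[c("X", paste0("X_ns", seq_len(int_df)))]
  true_er <- function(times) {
    basis <- .time_basis_at(design, times)
    100 * expm1(drop(cbind(1, basis) %*% b_int))
  }
  list(covariates = covariates, series = series, design = design,
       beta_true = beta, t0_index = t0_index, true_er = true_er)
}
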