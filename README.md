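# pdcount

Corrected inference for **parameter-driven count time series**: Poisson
regression for serially correlated counts (daily injuries, deaths,
admissions) where the dependence comes from an unobserved latent
stationary Gaussian AR(1) process in the log mean,

    Y_t | alpha_t ~ Poisson(exp(alpha_t + x_t' beta)),
    alpha_t ~ AR(1) with mean -sigma_alpha^2/2, variance sigma_alpha^2,
    lag-1 autocorrelation rho_alpha.

The ordinary Poisson GLM still estimates `beta` consistently, but its
standard errors ignore the latent process and are too small — type I
error inflates and intervention effects look spuriously significant.
`pdcount` provides two covariance corrections built on the sandwich

    Var(beta_hat) = Omega_I^{-1} + Omega_I^{-1} Omega_II Omega_I^{-1},

where `Omega_II` carries the latent autocovariance estimated by moment
methods:

* **UB** — the classical unbiased-correction estimator, using the lag-1
  autocorrelation estimate as the AR(1) truth. Reliable at modest
  autocorrelation, but the lag-1 moment estimator is biased downward when
  `rho_alpha >= 0.6`, so UB-based tests stay anti-conservative.
* **MSRC** (maximum significant rho correction) — Z-tests the
  autocorrelation estimates at lags 1..5, converts every significant lag
  to an order-1 equivalent through the AR(1) root relation, and plugs in
  the **maximum**. This counters the downward bias and holds the 5% test
  size once the series has a few hundred points, at a small cost in power.

The package is aimed at interrupted time-series (ITS) intervention
evaluation on daily count data and includes: the parameter-driven
simulator, a Monte Carlo harness for type-I-error/power studies, a
daily-count design builder (harmonic seasonality, day-of-week, holidays,
precipitation, temperature splines, offsets, time-varying intervention
effect), a synthetic daily-count generator with known truth, and
time-varying excess-risk curves with delta-method intervals.

## Worked example

Simulate an ITS study of length 340 with a strong latent autocorrelation
(`sigma_alpha^2 = 0.5`, `rho_alpha = 0.8`) and a level change of 0.4 at
mid-series, then compare naive and corrected inference:

```r
library(pdcount)

design <- build_its_design(340, t0 = 170, scale_time = TRUE)
alpha  <- simulate_latent_ar1(340, sigma2_alpha = 0.5, rho_alpha = 0.8,
                              seed = 2024)
series <- simulate_counts(as.matrix(design), beta = c(1, 1, 0.4, 0),
                          alpha, seed = 2025)

fit <- fit_poisson_glm(series)
tidy(fit)          # naive GLM standard errors
#>   term      estimate std.error statistic  p.value
#> 1 intercept    0.645    0.0976      6.61 3.91e-11
#> 2 t            2.00     0.301       6.65 2.96e-11
#> 3 X            0.681    0.0892      7.63 2.27e-14
#> 4 Xt          -1.83     0.342      -5.34 9.09e- 8

tidy(msrc_correct(fit))   # MSRC-corrected
#>   term      estimate std.error statistic p.value method
#> 1 intercept    0.645     0.289      2.23  0.0256 MSRC
#> 2 t            2.00      0.977      2.05  0.0408 MSRC
#> 3 X            0.681     0.374      1.82  0.0688 MSRC
#> 4 Xt          -1.83      1.37      -1.34  0.182  MSRC
```

The point estimates are identical; only the uncertainty changes. The
naive GLM calls every coefficient overwhelmingly significant — including
the spurious trend-change term `Xt`, whose true coefficient is 0, at
p = 9e-8. After the MSRC correction the standard errors are ~4x larger
and the evidence is far more guarded. `glance(msrc_correct(fit))` reports
the nuisance estimates behind the correction (here
`sigma2_alpha = 0.34`, selected `rho_alpha = 0.79`, truncation lag 57).

Monte Carlo operating characteristics and the intervention pipeline:

```r
res <- run_type1_experiment(simulation_config(
  n_grid = 340, sigma2_grid = 0.5, rho_grid = c(0.2, 0.8), n_reps = 2000))
autoplot(res)                     # rejection-rate curves per method

syn <- synthesize_rti_data(n_days = 1461, sigma2_alpha = 0.3,
                           rho_alpha = 0.6, er_step = -0.4, seed = 1)
fit <- fit_poisson_glm(syn$series)
er  <- excess_risk_curve(fit, msrc_correct(fit), syn$design,
                         times = c(500, 900, 1300))
autoplot(er)                      # excess risk (%) with 95% CI ribbon
```

A thin command-line front end for the harness and the ITS pipeline is in
`inst/cli/pdcount.R` (subcommands `table1`, `power`, `its`).

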