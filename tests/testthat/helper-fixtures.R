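# Shared fixtures: small simulated ITS datasets and fitted models.

its_data <- function(n, sigma2_alpha, rho_alpha, beta = c(1, 1, 0, 0),
                     seed = 1, t0 = n %/% 2) {
  X <- as.matrix(build_its_design(n, t0, scale_time = TRUE))
  alpha <- simulate_latent_ar1(n, sigma2_alpha, rho_alpha, seed = seed)
  simulate_counts(X, beta, alpha, seed = seed + 1L)
}

its_fit <- function(n = 200, sigma2_alpha = 0.5, rho_alpha = 0.6,
                    beta = c(1, 1, 0, 0), seed = 1) {
  fit_poisson_glm(its_data(n, sigma2_alpha, rho_alpha, beta, seed))
}

# brute-force Omega_II double sum over all (t, s) pairs with |s - t| <= L
omega_II_brute <- function(x, mu, gamma_fun, L) {
  n <- nrow(x)
  p <- ncol(x)
  om <- matrix(0, p, p)
  for (t in seq_len(n)) {
    for (s in seq_len(n)) {
      if (abs(s - t) <= L) {
        om <- om + x[t, ] %*% t(x[s, ]) * mu[t] * mu[s] * gamma_fun(abs(s - t))
      }
    }
  }
  om
}
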