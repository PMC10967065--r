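#' Z test of a lag-h autocorrelation estimate
#'
#' Tests \eqn{H_0: \rho_w(h) = 0} against positive autocorrelation (the
#' alternative of interest, since the maximum rule and the AR(1) root
#' transform are only meaningful for positive dependence). The statistic is
#' \eqn{z = \hat\rho_w(h)/\sqrt{\hat V}} by default; `denominator =
#' "variance"` divides by \eqn{\hat V} itself instead, for sensitivity.
#'
#' @param rho_h Autocorrelation estimate.
#' @param var_h Its estimated sampling variance (> 0).
#' @param level Significance level (default 0.01).
#' @param two_sided Use a two-sided test? Default one-sided (upper tail).
#' @param denominator `"sd"` (standard Z statistic) or `"variance"`.
#' @return A list with `z` and `significant`.
#' @examples
#' z_test_rho(0.3, 0.01) # z = 3 > 2.326, significant
#' @export
z_test_rho <- function(rho_h, var_h, level = 0.01, two_sided = FALSE,
                       denominator = c("sd", "variance")) {
  stopifnot(var_h > 0)
  denominator <- match.arg(denominator)
  z <- rho_h / switch(denominator, sd = sqrt(var_h), variance = var_h)
  significant <- if (two_sided) {
    abs(z) > stats::qnorm(1 - level / 2)
  } else {
    z > stats::qnorm(1 - level)
  }
  list(z = z, significant = significant)
}

#' Order-1 candidate from a lag-h autocorrelation estimate
#'
#' Under a latent AR(1) the lag-h autocorrelation is the h-th power of the
#' lag-1 value, so each lag yields a candidate order-1 estimate by an h-th
#' root. By default the root is taken on the latent (alpha) scale: map
#' \eqn{\hat\rho_w(h)} to the alpha scale with the exponential transform,
#' take the h-th root, map back. `scale = "w"` roots \eqn{\rho_w} directly
#' (sensitivity option). An even root of a negative value is inadmissible
#' and returns `NA`.
#'
#' @param rho_w_h w-scale lag-h autocorrelation estimate.
#' @param sigma2_w w-scale variance estimate (> 0).
#' @param h Lag (>= 1; h = 1 is the identity).
#' @param scale `"alpha"` (default) or `"w"`.
#' @return w-scale order-1 candidate, or `NA_real_` if inadmissible.
#' @examples
#' # alpha-scale 0.64 at lag 2 -> alpha-scale 0.8 -> w-scale 0.758
#' s2a <- 0.5
#' candidate_rho1(alpha_to_w_rho(0.64, s2a), alpha_to_w_variance(s2a), h = 2)
#' @export
candidate_rho1 <- function(rho_w_h, sigma2_w, h, scale = c("alpha", "w")) {
  stopifnot(h >= 1, sigma2_w > 0)
  scale <- match.arg(scale)
  if (h == 1) return(rho_w_h)
  root <- function(v) {
    if (v >= 0) return(v^(1 / h))
    if (h %% 2 == 0) return(NA_real_)
    -((-v)^(1 / h))
  }
  if (scale == "w") return(root(rho_w_h))
  s2a <- w_to_alpha_variance(sigma2_w)
  if (1 + rho_w_h * sigma2_w <= 0) return(NA_real_)
  ra <- w_to_alpha_rho(rho_w_h, s2a)
  r1 <- root(ra)
  if (is.na(r1)) return(NA_real_)
  alpha_to_w_rho(min(r1, 1), s2a)
}

#' Maximum significant autocorrelation (MSRC) selection
#'
#' The selection rule at the heart of the MSRC covariance correction: test
#' \eqn{\hat\rho_w(h)} for h = 1..H_max with a Z test at `level`, transform
#' each significant estimate to an order-1 candidate via the AR(1) root
#' relation, and take the maximum (ties broken at the lowest lag). When no
#' lag is significant the rule falls back to the order-1 estimate, so the
#' correction degrades gracefully to the classical unbiased correction.
#'
#' @param nuisance A list with components `rho_w` (vector over lags
#'   1..H_max), `rho_var` (matching variances) and `sigma2_w`, as produced
#'   inside [ub_correct()] (see the `nuisance` element of its result).
#' @param level Significance level of the per-lag Z test.
#' @param two_sided,denominator Passed to [z_test_rho()]; the selection rule
#'   defaults to the two-sided critical value (2.576 at level 0.01), which
#'   calibrates the frequency of higher-lag selection against the latent
#'   AR(1) truth; `two_sided = FALSE` is a less strict variant.
#' @param scale Passed to [candidate_rho1()].
#' @return A list of class `msrc_selection`: `z_stats`, `significant`,
#'   `candidates`, `rho_msrc`, `selected_lag`, `fallback_used`.
#' @export
msrc_rho <- function(nuisance, level = 0.01, two_sided = TRUE,
                     denominator = "sd", scale = "alpha") {
  rho <- nuisance$rho_w
  v <- nuisance$rho_var
  s2w <- nuisance$sigma2_w
  stopifnot(length(rho) == length(v), length(rho) >= 1)
  hmax <- length(rho)
  zt <- lapply(seq_len(hmax), function(h) {
    z_test_rho(rho[h], v[h], level = level, two_sided = two_sided,
               denominator = denominator)
  })
  z <- vapply(zt, `[[`, 0, "z")
  sig <- vapply(zt, `[[`, TRUE, "significant")
  cand <- rep(NA_real_, hmax)
  for (h in which(sig)) {
    cand[h] <- candidate_rho1(rho[h], s2w, h, scale = scale)
  }
  ok <- which(!is.na(cand))
  if (length(ok)) {
    sel <- ok[which.max(cand[ok])] # which.max takes the first among ties
    rho_msrc <- cand[sel]
    fallback <- FALSE
  } else {
    sel <- 1L
    rho_msrc <- rho[1]
    fallback <- TRUE
  }
  structure(
    list(z_stats = z, significant = sig, candidates = cand,
         rho_msrc = rho_msrc, selected_lag = sel, fallback_used = fallback),
    class = "msrc_selection"
  )
}

#' @export
print.msrc_selection <- function(x, ...) {
  cat("MSRC lag selection (H_max =", length(x$z_stats), ")\n")
  print(tibble::tibble(
    lag = seq_along(x$z_stats), z = x$z_stats,
    significant = x$significant, candidate = x$candidates
  ))
  cat("selected rho_w =", format(x$rho_msrc), "at lag", x$selected_lag,
      if (x$fallback_used) "(fallback: no significant lag)" else "", "\n")
  invisible(x)
}
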