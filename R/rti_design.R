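# Design matrix for daily injury-count intervention analysis: harmonic
# seasonality, day-of-week, holiday and precipitation categories, a natural
# cubic spline of temperature, a linear trend, and an intervention main
# effect with a spline-of-time interaction for a time-varying effect.

.dow_levels <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
.holiday_levels <- c("none", "spring_festival", "other")
.precip_levels <- c("none", "mild", "severe")

.as_level <- function(x, levels, what) {
  x <- as.character(x)
  bad <- setdiff(unique(x), levels)
  if (length(bad)) {
    stop("Unseen ", what, " levels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = levels)
}

#' Categorise hourly-rate precipitation
#'
#' Cut-offs: `none` = 0.0 mm/h, `mild` = (0, 2.5] mm/h, `severe` > 2.5 mm/h.
#'
#' @param precip_mm_h Non-negative precipitation rate in mm/h.
#' @return Factor with levels none/mild/severe.
#' @export
precip_category <- function(precip_mm_h) {
  stopifnot(all(precip_mm_h >= 0))
  factor(ifelse(precip_mm_h == 0, "none",
                ifelse(precip_mm_h <= 2.5, "mild", "severe")),
         levels = .precip_levels)
}

#' Build the daily intervention-analysis design matrix
#'
#' Columns: intercept; `2k` harmonic terms \eqn{\sin(2\theta\pi t/T),
#' \cos(2\theta\pi t/T)} for seasonality; six day-of-week contrasts
#' (reference Monday); two holiday contrasts (reference non-holiday); two
#' precipitation contrasts (reference no precipitation); `temp_df`
#' natural-cubic-spline columns for mean temperature; a linear trend (scaled
#' by n); the intervention indicator; and the intervention interacted with
#' an `int_df`-df natural cubic spline of time over the full study period
#' (the time-varying intervention effect). The log exposure
#' `log(pop_car_product)` becomes the `offset` column. Spline knots are at
#' equally spaced quantiles with boundary knots at the data range.
#'
#' @param cov Daily covariate table with columns `date`,
#'   `pop_car_product` (> 0), `dow` (Mon..Sun), `holiday`
#'   (none/spring_festival/other), `precip_cat` (none/mild/severe; or supply
#'   `precip_mm_h` and it is categorised), `temp`, `intervention` (0/1).
#' @param k Number of harmonic pairs (default 2).
#' @param period Period of the harmonics in days (default 365.25).
#' @param temp_df Temperature spline degrees of freedom (default 3).
#' @param int_df Time-spline degrees of freedom in the intervention
#'   interaction (default 5).
#' @return A design tibble (including `offset`), ready to be combined with a
#'   count column via [as_count_series()]. Attributes `time_basis` (spline
#'   knots for later evaluation), `intervention_cols`, `t0_index`, `n`.
#' @export
build_rti_design <- function(cov, k = 2, period = 365.25, temp_df = 3,
                             int_df = 5) {
  stopifnot(is.data.frame(cov), k >= 1)
  need <- c("date", "pop_car_product", "dow", "holiday", "temp",
            "intervention")
  miss <- setdiff(need, names(cov))
  if (length(miss)) {
    stop("Missing covariate columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"precip_cat" %in% names(cov)) {
    if (!"precip_mm_h" %in% names(cov)) {
      stop("Supply `precip_cat` or `precip_mm_h`.", call. = FALSE)
    }
    cov$precip_cat <- precip_category(cov$precip_mm_h)
  }
  if (any(cov$pop_car_product <= 0)) {
    stop("Exposure `pop_car_product` must be positive.", call. = FALSE)
  }
  n <- nrow(cov)
  t <- seq_len(n)
  X <- as.numeric(cov$intervention > 0)

  harm <- do.call(cbind, lapply(seq_len(k), function(th) {
    m <- cbind(sin(2 * th * pi * t / period), cos(2 * th * pi * t / period))
    colnames(m) <- paste0(c("sin", "cos"), th)
    m
  }))

  dow <- .as_level(cov$dow, .dow_levels, "day-of-week")
  hol <- .as_level(cov$holiday, .holiday_levels, "holiday")
  prc <- .as_level(cov$precip_cat, .precip_levels, "precipitation")
  cat_mat <- function(f, prefix) {
    m <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(m) <- paste0(prefix, "_", levels(f)[-1])
    m
  }

  temp_ns <- splines::ns(cov$temp, df = temp_df)
  colnames(temp_ns) <- paste0("temp_ns", seq_len(temp_df))
  time_ns <- splines::ns(t, df = int_df)
  int_ns <- X * time_ns
  colnames(int_ns) <- paste0("X_ns", seq_len(int_df))

  out <- tibble::as_tibble(as.data.frame(cbind(
    intercept = 1, harm,
    cat_mat(dow, "dow"), cat_mat(hol, "holiday"), cat_mat(prc, "precip"),
    temp_ns,
    t = t / n,
    X = X,
    int_ns
  )))
  out$offset <- log(cov$pop_car_product)
  attr(out, "time_basis") <- list(
    knots = attr(time_ns, "knots"),
    Boundary.knots = attr(time_ns, "Boundary.knots"),
    int_df = int_df
  )
  attr(out, "intervention_cols") <- c("X", colnames(int_ns))
  attr(out, "t0_index") <- if (any(X > 0)) min(which(X > 0)) else NA_integer_
  attr(out, "n") <- n
  out
}

# Evaluate the intervention time-spline basis at arbitrary times using the
# knots stored on the design (no extrapolation).
.time_basis_at <- function(design, times) {
  tb <- attr(design, "time_basis")
  if (is.null(tb)) stop("Design carries no time-spline basis.", call. = FALSE)
  if (any(times < tb$Boundary.knots[1] | times > tb$Boundary.knots[2])) {
    stop("`times` outside the spline boundary: no extrapolation.",
         call. = FALSE)
  }
  b <- splines::ns(times, knots = tb$knots,
                   Boundary.knots = tb$Boundary.knots)
  unname(b[, , drop = FALSE])
}
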