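# Demographic summary measures over posterior draws: total fertility rate,
# life expectancy at birth from an abridged life table, and empirical
# quantile summaries with nested predictive intervals.

#' Total fertility rate from age-specific rates
#'
#' `TFR_r = 5 * sum of annual age-specific fertility rates` over the
#' reproductive window (five-year age groups).
#'
#' @param f region x age matrix of annual fertility rates covering either
#'   all age groups (zero outside the window) or exactly the window.
#' @param registry the [dimension_registry()].
#' @return named vector of TFRs per region.
#' @export
tfr <- function(f, registry) {
  f <- as.matrix(f)
  win <- registry$reproductive_window
  nw <- win[2] - win[1] + 1
  if (ncol(f) == n_ages(registry)) {
    outside <- f[, -(win[1]:win[2]), drop = FALSE]
    if (any(outside != 0))
      stop_mrpop("nonzero fertility rates outside the reproductive window")
    f <- f[, win[1]:win[2], drop = FALSE]
  } else if (ncol(f) != nw) {
    stop_mrpop("f must have %d (window) or %d (all) age columns", nw,
               n_ages(registry))
  }
  stats::setNames(5 * rowSums(f), registry$regions[seq_len(nrow(f))])
}

#' Life expectancy at birth from an abridged life table
#'
#' Builds a period life table on five-year age groups with the linear
#' person-years assumption: `q_x = 5 d / (1 + 2.5 d)`,
#' `L_x = 5 (l_x + l_{x+5}) / 2` for closed groups, and open-ended closure
#' `L_z = l_z / d_z`; returns `e0 = sum(L) / l_0`.
#'
#' @param d vector of annualised age-specific mortality rates, one per age
#'   group (last open-ended).
#' @param registry the [dimension_registry()] (for the group count).
#' @return life expectancy at birth in years.
#' @export
life_expectancy_at_birth <- function(d, registry) {
  z <- n_ages(registry)
  if (length(d) != z) stop_mrpop("need one mortality rate per age group")
  if (any(d < 0)) stop_mrpop("mortality rates must be non-negative")
  q <- 5 * d[-z] / (1 + 2.5 * d[-z])
  l <- cumprod(c(1, 1 - q))       # l at ages 0, 5, ..., z
  Lclosed <- 5 * (l[-z] + l[-1]) / 2
  if (d[z] <= 0 && l[z] > 0)
    stop_mrpop("open-ended mortality rate must be positive when survivors remain")
  Lopen <- if (l[z] > 0) l[z] / d[z] else 0
  sum(Lclosed) + Lopen
}

#' Empirical quantile summary of draw-indexed values
#'
#' Computes the median and symmetric predictive intervals at the requested
#' coverage levels using linear-interpolation quantiles, plus a utility
#' percentile lookup for an external value.  Intervals are nested by
#' construction.
#'
#' @param values numeric vector (or matrix `draws x variables`) of draws.
#' @param levels interval coverage levels, default `c(0.5, 0.8, 0.95)`.
#' @param observed optional external value(s) whose percentile within the
#'   draws is reported.
#' @return data frame with `median`, `lower<level>` / `upper<level>` columns
#'   and optionally `percentile_observed`.
#' @export
summarize_draws <- function(values, levels = c(0.5, 0.8, 0.95),
                            observed = NULL) {
  m <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  if (nrow(m) < 2) stop_mrpop("need at least 2 draws")
  out <- data.frame(median = apply(m, 2, mrpop_quantile, probs = 0.5))
  for (lv in sort(levels)) {
    a <- (1 - lv) / 2
    out[[sprintf("lower%g", lv * 100)]] <- apply(m, 2, mrpop_quantile, probs = a)
    out[[sprintf("upper%g", lv * 100)]] <- apply(m, 2, mrpop_quantile, probs = 1 - a)
  }
  if (!is.null(observed)) {
    out$percentile_observed <- vapply(seq_len(ncol(m)), function(j)
      100 * mean(m[, j] <= observed[min(j, length(observed))]), 0)
  }
  out
}

#' TFR distribution from a fertility forecast
#'
#' @param forecast an `mrpop_forecast` for fertility.
#' @param year forecast year to summarise.
#' @return matrix `draws x regions` of TFRs.
#' @export
tfr_draws <- function(forecast, year) {
  stopifnot(forecast$component == "fertility")
  reg <- forecast$registry
  sel <- forecast$cells$year == year
  ages <- reproductive_ages(reg)
  t(apply(forecast$mu[, sel, drop = FALSE], 1, function(v) {
    f <- matrix(v, n_regions(reg), length(ages))
    tfr(f, reg)
  }))
}

#' Life expectancy distribution from a mortality forecast
#'
#' @param forecast an `mrpop_forecast` for mortality.
#' @param year forecast year.
#' @param sex `"M"` or `"F"`.
#' @return matrix `draws x regions` of life expectancies at birth.
#' @export
e0_draws <- function(forecast, year, sex) {
  stopifnot(forecast$component == "mortality")
  reg <- forecast$registry
  sel <- forecast$cells$year == year & forecast$cells$sex == sex
  n <- n_regions(reg); z <- n_ages(reg)
  t(apply(forecast$mu[, sel, drop = FALSE], 1, function(v) {
    d <- matrix(v, n, z)
    vapply(seq_len(n), function(r) life_expectancy_at_birth(d[r, ], reg), 0)
  }))
}
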