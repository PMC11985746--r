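# Latent time-effect processes: densities, priors and forecasting for the
# univariate AR(1) (with or without drift), random walk with drift, and the
# sex-paired bivariate random walk / VAR(1) with decomposed covariance.

#' AR(1) log density of a latent time path
#'
#' `kappa_t ~ Normal(phi1 + phi2 * kappa_{t-1}, sigma^2)` for `t = 2..T`,
#' with the first value fixed at zero for identifiability.  Setting
#' `phi2 = 1` gives the random-walk-with-drift density.
#'
#' @param kappa numeric path of length `T >= 2` with `kappa[1] == 0`.
#' @param phi1 drift.
#' @param phi2 autoregressive parameter.
#' @param sigma
#'   innovation standard deviation (> 0).
#' @return scalar log density.
#' @export
ar1_logdensity <- function(kappa, phi1, phi2, sigma) {
  if (sigma <= 0) stop_mrpop("sigma must be positive")
  T <- length(kappa)
  if (T < 2) stop_mrpop("path must have length >= 2")
  if (abs(kappa[1]) > 1e-12)
    stop_mrpop("kappa[1] must be 0 (first-period identification)")
  sum(stats::dnorm(kappa[-1], phi1 + phi2 * kappa[-T], sigma, log = TRUE))
}

# Bivariate (sex-paired) path log density: rows M, F; drift = c(phi11,
# phi12); ar = c(phi21, phi22) (1,1 for the random walk); Sigma 2x2.
bivariate_kappa_logdensity <- function(kappa, drift, ar, Sigma) {
  T <- ncol(kappa)
  if (any(abs(kappa[, 1]) > 1e-12)) stop_mrpop("kappa[,1] must be 0")
  Qi <- solve(Sigma)
  ld <- 0
  for (t in 2:T) {
    e <- kappa[, t] - drift - ar * kappa[, t - 1]
    ld <- ld - 0.5 * (2 * log(2 * pi) + determinant(Sigma)$modulus +
                        drop(crossprod(e, Qi %*% e)))
  }
  as.numeric(ld)
}

#' Covariance from a correlation matrix and marginal standard deviations
#'
#' Recomposes `Sigma = D Omega D` where `D = diag(sigmas)`; the result has
#' the given marginal standard deviations and the correlations of `Omega`.
#'
#' @param Omega symmetric correlation matrix (unit diagonal, entries in
#'   `[-1, 1]`, positive definite).
#' @param sigmas positive marginal standard deviations.
#' @return covariance matrix.
#' @export
cov_from_corr <- function(Omega, sigmas) {
  Omega <- as.matrix(Omega)
  if (!isTRUE(all.equal(Omega, t(Omega))) || any(abs(diag(Omega) - 1) > 1e-10))
    stop_mrpop("Omega must be symmetric with unit diagonal")
  if (any(abs(Omega) > 1 + 1e-10)) stop_mrpop("correlations must lie in [-1, 1]")
  if (any(sigmas <= 0)) stop_mrpop("sigmas must be positive")
  ev <- eigen(Omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop_mrpop("Omega must be positive definite")
  D <- diag(sigmas, nrow = length(sigmas))
  D %*% Omega %*% D
}

#' LKJ log density (unnormalised) of a correlation matrix
#'
#' Proportional to `(eta - 1) * log det(Omega)`; `eta = 1` is uniform over
#' valid correlation matrices, `eta > 1` shrinks towards the identity.
#'
#' @param Omega correlation matrix.
#' @param eta concentration (> 0).
#' @return log density up to the LKJ normalising constant.
#' @export
lkj_logdensity <- function(Omega, eta) {
  Omega <- as.matrix(Omega)
  if (any(abs(diag(Omega) - 1) > 1e-10))
    stop_mrpop("Omega must have unit diagonal")
  ev <- eigen(Omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop_mrpop("Omega must be positive definite")
  (eta - 1) * sum(log(ev))
}

#' Joint prior log density of time-series dynamics parameters
#'
#' Drift `phi1 ~ Normal(0, 2^2)`; autoregression `phi2 ~ Normal(0.5, 0.2^2)`
#' truncated to `[0, 1]` (log density `-Inf` outside); innovation sd
#' half-standard-normal; for sex-paired series, marginal sds
#' `sigma_M, sigma_F ~ Normal+(0, 1)` and correlation `Omega ~ LKJ(2)`.
#' Only the parameters present in `params` contribute.
#'
#' @param params named list with any of `phi1`, `phi2` (each possibly
#'   vector-valued for sex-paired drifts/autoregressions), `sigma`,
#'   `sigma_M`, `sigma_F`, `rho` (2x2 correlation), `lkj_eta` (default 2).
#' @return scalar log density (`-Inf` if a truncation or support constraint
#'   is violated).
#' @export
dynamics_prior_logdensity <- function(params) {
  ld <- 0
  if (!is.null(params$phi1))
    ld <- ld + sum(stats::dnorm(params$phi1, 0, 2, log = TRUE))
  if (!is.null(params$phi2)) {
    if (any(params$phi2 < 0 | params$phi2 > 1)) return(-Inf)
    Z <- stats::pnorm(1, 0.5, 0.2) - stats::pnorm(0, 0.5, 0.2)
    ld <- ld + sum(stats::dnorm(params$phi2, 0.5, 0.2, log = TRUE) - log(Z))
  }
  for (s in c("sigma", "sigma_M", "sigma_F")) {
    if (!is.null(params[[s]])) {
      if (any(params[[s]] <= 0)) return(-Inf)
      ld <- ld + sum(stats::dnorm(params[[s]], 0, 1, log = TRUE) + log(2))
    }
  }
  if (!is.null(params$rho)) {
    Omega <- matrix(c(1, params$rho, params$rho, 1), 2, 2)
    if (abs(params$rho) >= 1) return(-Inf)
    ld <- ld + lkj_logdensity(Omega, params$lkj_eta %||% 2)
  }
  ld
}

#' Simulate a latent time path forward
#'
#' Iterates the fitted process `horizon` steps beyond the last observed
#' value, drawing one innovation per step (set the innovation sd(s) to zero
#' for the deterministic recursion).  Uses R's global RNG stream; seed the
#' caller for reproducibility.
#'
#' @param spec a [kappa_spec()].
#' @param params dynamics parameters: `phi1`, `phi2`, `sigma` for univariate
#'   series; `phi1` (length 2), `phi2` (length 2), `sigma_M`, `sigma_F`,
#'   `rho` for sex-paired series.
#' @param last_kappa final observed value (length 2 for sex-paired series).
#' @param horizon number of future periods (>= 1).
#' @return numeric vector of length `horizon` (matrix `2 x horizon` for
#'   sex-paired series).
#' @export
forecast_path <- function(spec, params, last_kappa, horizon) {
  stopifnot(horizon >= 1)
  if (spec$sex_paired) {
    drift <- rep_len(params$phi1 %||% 0, 2)
    ar <- rep_len(if (spec$dynamics == "mrw_drift") 1 else params$phi2, 2)
    noise_free <- params$sigma_M <= 0 && params$sigma_F <= 0
    Lc <- if (noise_free) matrix(0, 2, 2) else
      t(chol(cov_from_corr(matrix(c(1, params$rho, params$rho, 1), 2, 2),
                           c(params$sigma_M, params$sigma_F))))
    out <- matrix(0, 2, horizon, dimnames = list(c("M", "F"), NULL))
    prev <- as.numeric(last_kappa)
    for (h in seq_len(horizon)) {
      prev <- drift + ar * prev + drop(Lc %*% stats::rnorm(2))
      out[, h] <- prev
    }
    return(out)
  }
  phi1 <- if (kappa_has_drift(spec)) params$phi1 %||% 0 else 0
  phi2 <- switch(spec$dynamics, rw_drift = 1, params$phi2)
  sigma <- params$sigma
  out <- numeric(horizon)
  prev <- as.numeric(last_kappa)
  for (h in seq_len(horizon)) {
    prev <- phi1 + phi2 * prev + if (sigma > 0) stats::rnorm(1, 0, sigma) else 0
    out[h] <- prev
  }
  out
}
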