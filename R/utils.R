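# Internal numerical utilities shared across the samplers and engines.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mrpop <- function(...) stop(sprintf(...), call. = FALSE)

#' Univariate slice sampler (stepping-out and shrinkage)
#'
#' Used for scale and correlation parameters whose full conditionals are
#' log-concave-ish but non-conjugate (half-t / half-normal scales, the
#' correlation of a 2x2 LKJ-prior matrix).  No tuning is required beyond an
#' initial step width.
#'
#' @param x0 current value (must satisfy `logf(x0) > -Inf`).
#' @param logf log target density (up to a constant).
#' @param w initial interval width.
#' @param lower,upper support bounds.
#' @param max_steps stepping-out cap.
#' @return a new value distributed according to `logf`.
#' @keywords internal
slice_sample1 <- function(x0, logf, w = 1, lower = -Inf, upper = Inf,
                          max_steps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop_mrpop("slice sampler started outside support")
  y <- f0 + log(stats::runif(1))
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  k <- max_steps
  while (k > 0 && L > lower && logf(max(L, lower)) > y) {
    L <- L - w
    k <- k - 1
  }
  k <- max_steps
  while (k > 0 && R < upper && logf(min(R, upper)) > y) {
    R <- R + w
    k <- k - 1
  }
  L <- max(L, lower)
  R <- min(R, upper)
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

# Draw from Normal(mean, sd) truncated to [a, b] by inverse CDF.
rtruncnorm1 <- function(mean, sd, a, b) {
  pa <- stats::pnorm(a, mean, sd)
  pb <- stats::pnorm(b, mean, sd)
  if (pb - pa < 1e-14) {
    # numerically degenerate: return the nearest bound
    return(if (mean < a) a else b)
  }
  stats::qnorm(pa + stats::runif(1) * (pb - pa), mean, sd)
}

# log density of a half-t distribution (location 0) evaluated at x > 0.
dhalf_t <- function(x, df, scale, log = TRUE) {
  ld <- stats::dt(x / scale, df = df, log = TRUE) - log(scale) + log(2)
  ld[x < 0] <- -Inf
  if (log) ld else exp(ld)
}

# Draw from MVN given precision matrix Q and linear term b: N(Q^-1 b, Q^-1).
rmvnorm_precision <- function(b, Q) {
  U <- chol(Q)
  mu <- backsolve(U, backsolve(U, b, transpose = TRUE))
  z <- stats::rnorm(length(b))
  mu + backsolve(U, z)
}

# Split-Rhat (Gelman et al.) for a draws matrix iters x chains.
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(xs)
  nn <- nrow(xs)
  means <- colMeans(xs)
  vars <- apply(xs, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W <= 0) return(1)
  sqrt((((nn - 1) / nn) * W + B / nn) / W)
}

# Crude effective sample size via initial-positive-sequence autocorrelation.
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  ess_one <- function(v) {
    v <- v - mean(v)
    s2 <- sum(v^2) / length(v)
    if (s2 == 0) return(length(v))
    acf_sum <- 0
    for (k in seq_len(min(length(v) - 2, 200))) {
      rk <- sum(v[1:(length(v) - k)] * v[(k + 1):length(v)]) / (length(v) * s2)
      if (rk < 0.05) break
      acf_sum <- acf_sum + rk
    }
    length(v) / (1 + 2 * acf_sum)
  }
  sum(apply(x, 2, ess_one))
}

# Empirical quantile with linear interpolation (type 7), the single quantile
# convention used throughout the package.
mrpop_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}
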