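# Latent time-effect processes: densities, covariance decomposition,
# priors and forecasting.

test_that("AR(1) log density equals the sum of scalar normal log pdfs", {
  kappa <- c(0, 0.4, -0.1)
  phi1 <- 0.2; phi2 <- 0.6; sigma <- 0.3
  ref <- dnorm(0.4, 0.2 + 0.6 * 0, 0.3, TRUE) +
         dnorm(-0.1, 0.2 + 0.6 * 0.4, 0.3, TRUE)
  expect_equal(ar1_logdensity(kappa, phi1, phi2, sigma), ref)
  expect_error(ar1_logdensity(c(1, 0), 0, 0.5, 1), "kappa\\[1\\]")
  expect_error(ar1_logdensity(c(0, 1), 0, 0.5, 0), "positive")
})

test_that("phi2 = 1 reduces the AR(1) density to a random walk with drift", {
  set.seed(2)
  kappa <- c(0, cumsum(rnorm(5, 0.2, 0.5)))
  rw_ref <- sum(dnorm(diff(kappa), 0.2, 0.5, log = TRUE))
  expect_equal(ar1_logdensity(kappa, 0.2, 1, 0.5), rw_ref)
})

test_that("a flat path at the process mean maximises the density over paths", {
  flat <- c(0, 0, 0)
  perturbed <- c(0, 0.1, -0.05)
  expect_gt(ar1_logdensity(flat, 0, 0.5, 0.3),
            ar1_logdensity(perturbed, 0, 0.5, 0.3))
})

test_that("noise-free forecasts follow the deterministic recursion", {
  ar <- kappa_spec("k", "ar1_drift")
  # fixed point phi1 / (1 - phi2) = 1 stays at 1
  f <- forecast_path(ar, list(phi1 = 0.5, phi2 = 0.5, sigma = 0), 1, 5)
  expect_equal(f, rep(1, 5))
  rw <- kappa_spec("k", "rw_drift")
  f2 <- forecast_path(rw, list(phi1 = 0.2, sigma = 0), 0, 3)
  expect_equal(f2, c(0.2, 0.4, 0.6))
})

test_that("AR(1) forecast variance converges to the stationary closed form", {
  ar <- kappa_spec("k", "ar1_drift")
  phi2 <- 0.6; sigma <- 0.4
  H <- 60
  set.seed(11)
  n <- 10000
  finals <- replicate(n, forecast_path(ar, list(phi1 = 0, phi2 = phi2,
                                                sigma = sigma), 0, H)[H])
  v_stat <- sigma^2 / (1 - phi2^2)
  # variance of the sample variance ~ 2 v^2 / n for Gaussian draws
  se <- sqrt(2 / n) * v_stat
  expect_lt(abs(var(finals) - v_stat), 3 * se)
})

test_that("random-walk forecast variance grows linearly in horizon", {
  rw <- kappa_spec("k", "rw_drift")
  set.seed(12)
  n <- 4000
  sims <- replicate(n, forecast_path(rw, list(phi1 = 0, sigma = 1), 0, 8))
  v <- apply(sims, 1, var)
  fit <- lm(v ~ seq_len(8))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.1)
  expect_lt(abs(v[8] / v[4] - 2), 0.25)
})

test_that("forecasts are reproducible given a seed", {
  ar <- kappa_spec("k", "ar1_drift")
  set.seed(5)
  a <- forecast_path(ar, list(phi1 = 0.1, phi2 = 0.7, sigma = 0.3), 0.5, 10)
  set.seed(5)
  b <- forecast_path(ar, list(phi1 = 0.1, phi2 = 0.7, sigma = 0.3), 0.5, 10)
  expect_identical(a, b)
})

test_that("covariance recomposition has the stated sds and correlations", {
  expect_equal(cov_from_corr(diag(2), c(1, 1)), diag(2))
  S <- cov_from_corr(matrix(c(1, 0.5, 0.5, 1), 2, 2), c(2, 1))
  expect_equal(S[1, 2], 1.0)
  expect_equal(sqrt(diag(S)), c(2, 1))
  # round trip: recovering the correlation reproduces Omega
  set.seed(3)
  for (i in 1:10) {
    rho <- runif(1, -0.9, 0.9); sds <- runif(2, 0.1, 3)
    Om <- matrix(c(1, rho, rho, 1), 2, 2)
    S <- cov_from_corr(Om, sds)
    expect_equal(cov2cor(S), Om, tolerance = 1e-12)
  }
  expect_error(cov_from_corr(matrix(c(1, 1.2, 1.2, 1), 2, 2), c(1, 1)),
               "positive definite|\\[-1, 1\\]")
})

test_that("LKJ density behaves as its closed form in 2x2", {
  I2 <- diag(2)
  Om <- function(r) matrix(c(1, r, r, 1), 2, 2)
  # eta = 1: uniform over correlation
  expect_equal(lkj_logdensity(Om(0.7), 1), lkj_logdensity(Om(-0.2), 1))
  expect_equal(lkj_logdensity(I2, 2), 0)
  expect_equal(lkj_logdensity(Om(0.9), 2) - lkj_logdensity(Om(0), 2),
               log(1 - 0.81), tolerance = 1e-10)
})

test_that("dynamics priors truncate and scale as specified", {
  expect_identical(dynamics_prior_logdensity(list(phi2 = -0.1)), -Inf)
  # phi2 mode at 0.5
  expect_gt(dynamics_prior_logdensity(list(phi2 = 0.5)),
            dynamics_prior_logdensity(list(phi2 = 0.9)))
  d1 <- dynamics_prior_logdensity(list(phi1 = 1))
  d0 <- dynamics_prior_logdensity(list(phi1 = 0))
  expect_equal(d1 - d0, -1 / (2 * 4), tolerance = 1e-12)
  expect_identical(dynamics_prior_logdensity(list(sigma = -1)), -Inf)
  expect_identical(dynamics_prior_logdensity(list(rho = 1.5)), -Inf)
})

test_that("sex-paired forecasting respects the covariance decomposition", {
  mrw <- kappa_spec("k", "mrw_drift")
  params <- list(phi1 = c(0.1, -0.1), sigma_M = 0.2, sigma_F = 0.3, rho = 0.8)
  set.seed(21)
  sims <- replicate(3000, forecast_path(mrw, params, c(0, 0), 1))
  expect_equal(sd(sims[1, 1, ]), 0.2, tolerance = 0.02)
  expect_equal(sd(sims[2, 1, ]), 0.3, tolerance = 0.03)
  expect_equal(cor(sims[1, 1, ], sims[2, 1, ]), 0.8, tolerance = 0.03)
  expect_equal(mean(sims[1, 1, ]), 0.1, tolerance = 0.02)
})
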