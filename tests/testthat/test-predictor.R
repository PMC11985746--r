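# Log-bilinear predictor: additivity, break terms, constraints and priors.

make_fert_setup <- function() {
  reg <- dimension_registry(c("A", "B"), seq(0, 85, 5), 2001:2005)
  spec <- default_model_spec("fertility")
  cells <- component_cell_grid_public(reg)
  list(reg = reg, spec = spec, cells = cells)
}

# small helper: fertility grid without reaching into internals
component_cell_grid_public <- function(reg) {
  ages <- reg$age_groups[reg$reproductive_window[1]:reg$reproductive_window[2]]
  g <- expand.grid(origin = reg$regions, age = ages, year = reg$years,
                   stringsAsFactors = FALSE)
  g$destination <- NA_character_; g$sex <- NA_character_
  g
}

zero_params_fert <- function(reg) {
  ages <- seq(15, 45, 5)
  list(c = 0,
       RA = numeric(2 * 7),
       A1 = numeric(7),
       A2 = rep(1 / 7, 7),
       R1 = numeric(2),
       R2 = rep(1 / 2, 2))
}

test_that("all-zero parameters give a zero predictor everywhere", {
  s <- make_fert_setup()
  params <- zero_params_fert(s$reg)
  kv <- list(kappa1 = numeric(5), kappa2 = numeric(5))
  M <- linear_predictor(s$spec, params, kv, s$cells, s$reg)
  expect_true(all(M == 0))
})

test_that("the predictor is additive in its terms", {
  s <- make_fert_setup()
  set.seed(1)
  params <- list(c = -3, RA = rnorm(14, 0, 0.2), A1 = rnorm(7, 0, 0.5),
                 A2 = constrain_bilinear_loadings(runif(6, 0, 0.3)),
                 R1 = rnorm(2), R2 = constrain_bilinear_loadings(0.7))
  kv <- list(kappa1 = c(0, cumsum(rnorm(4, 0, 0.2))),
             kappa2 = c(0, cumsum(rnorm(4, 0, 0.2))))
  M <- linear_predictor(s$spec, params, kv, s$cells, s$reg)
  # sum of single-term evaluations equals the joint evaluation
  Msum <- 0
  base <- zero_params_fert(s$reg)
  zero_kv <- list(kappa1 = numeric(5), kappa2 = numeric(5))
  for (nm in names(params)) {
    p1 <- base
    p1[[nm]] <- params[[nm]]
    kv1 <- zero_kv
    if (nm == "A2") kv1$kappa1 <- kv$kappa1
    if (nm == "R2") kv1$kappa2 <- kv$kappa2
    Msum <- Msum + linear_predictor(s$spec, p1, kv1, s$cells, s$reg)
  }
  expect_equal(M, Msum, tolerance = 1e-12)
})

test_that("bilinear arithmetic matches hand computation", {
  s <- make_fert_setup()
  params <- zero_params_fert(s$reg)
  params$c <- -3
  params$A1[2] <- 0.5          # age 20-24
  params$A2 <- c(0, 0.1, rep(0, 4), 0.9)  # sums to 1
  kv <- list(kappa1 = c(0, 2, 0, 0, 0), kappa2 = numeric(5))
  M <- linear_predictor(s$spec, params, kv, s$cells, s$reg)
  cell <- s$cells$age == 20 & s$cells$year == 2002 & s$cells$origin == "A"
  expect_equal(unique(M[cell]), -3 + 0.5 + 0.1 * 2)
})

test_that("a break indicator shifts the predictor only from its threshold year", {
  reg <- dimension_registry(c("A", "B"), seq(0, 85, 5), 2001:2006)
  spec <- default_model_spec("immigration", break_year = 2004)
  cells <- expand.grid(origin = c("A", "B"), age = seq(0, 85, 5),
                       sex = c("M", "F"), year = 2001:2006,
                       stringsAsFactors = FALSE)
  cells$destination <- NA_character_
  z <- 18
  params <- list(c = 0, Rbrk = c(0.3, 0), RA = numeric(2 * z),
                 AS1 = numeric(2 * z),
                 AS2 = rbind(rep(1 / z, z), rep(1 / z, z)),
                 R1 = numeric(2), R2 = rep(0.5, 2))
  kv <- list(kappa1 = matrix(0, 2, 6), kappa2 = numeric(6))
  M <- linear_predictor(spec, params, kv, cells, reg)
  a03 <- M[cells$origin == "A" & cells$year == 2003]
  a05 <- M[cells$origin == "A" & cells$year == 2005]
  a04 <- M[cells$origin == "A" & cells$year == 2004]
  b05 <- M[cells$origin == "B" & cells$year == 2005]
  expect_true(all(a05 - a03 == 0.3))
  expect_true(all(a04 - a03 == 0.3))  # active from the threshold year itself
  expect_true(all(b05 == 0))
})

test_that("constrained loadings always sum to one", {
  expect_equal(constrain_bilinear_loadings(rep(1 / 5, 4)), rep(1 / 5, 5))
  expect_equal(constrain_bilinear_loadings(c(1, 0)), c(1, 0, 0))
  set.seed(7)
  for (i in 1:20) {
    u <- rnorm(sample(1:25, 1))
    expect_equal(sum(constrain_bilinear_loadings(u)), 1, tolerance = 1e-12)
  }
})

test_that("bilinear prior matches its closed forms", {
  # L = 2: one free value, Psi = (2), covariance 1/(4*2) = 1/8
  u <- 0.3
  expect_equal(bilinear_prior_logdensity(u),
               dnorm(u, 0.5, sqrt(1 / 8), log = TRUE))
  # mode at 1/L
  expect_gt(bilinear_prior_logdensity(0.5), bilinear_prior_logdensity(0.2))
  # L = 3: brute-force via explicit 2x2 inverse
  u <- c(0.2, 0.5)
  Psi <- matrix(c(2, 1, 1, 2), 2, 2)
  Sigma <- solve(9 * Psi)
  d <- u - 1 / 3
  ref <- -log(2 * pi) - 0.5 * determinant(Sigma)$modulus -
    0.5 * drop(t(d) %*% solve(Sigma) %*% d)
  expect_equal(bilinear_prior_logdensity(u), as.numeric(ref), tolerance = 1e-10)
})

test_that("symmetric origin-destination prior equals a direct enumeration", {
  regions <- c("A", "B", "C")
  alpha <- c(0.5, -0.2, 0.9)          # pairs AB, AC, BC
  od1 <- c(0.4, 0.6, -0.1, 0.8, 1.0, -0.3)
  s <- 0.7
  got <- symmetric_od_prior(alpha, od1, s, regions)
  # enumerate the 6 ordered pairs by hand (order: BA CA AB CB AC BC
  # following origin-fastest enumeration of off-diagonal pairs)
  pair_means <- c(0.5, -0.2, 0.5, 0.9, -0.2, 0.9)
  expect_equal(got, sum(dnorm(od1, pair_means, s, log = TRUE)))
  # symmetry: n = 2 shares one alpha between both directions
  g2 <- symmetric_od_prior(0.3, c(1, 2), 1, c("A", "B"))
  expect_equal(g2, dnorm(1, 0.3, 1, TRUE) + dnorm(2, 0.3, 1, TRUE))
  # density maximal when od1 equals the expanded alpha
  at_mode <- symmetric_od_prior(alpha, pair_means, s, regions)
  expect_gt(at_mode, got)
})

test_that("Poisson-lognormal likelihood matches the pmf and handles edge cases", {
  # Poisson part: Y = 5, K = 100, mu = 0.05 so lambda = 5
  got <- poisson_lognormal_loglik(5, 100, log(0.05), M = log(0.05), sigma = 1)
  pois_ref <- 5 * log(5) - 5 - lfactorial(5)
  norm_ref <- dnorm(log(0.05), log(0.05), 1, log = TRUE)
  expect_equal(got, pois_ref + norm_ref, tolerance = 1e-12)
  # zero count: Poisson part is -lambda
  got0 <- poisson_lognormal_loglik(0, 1, log(2), M = log(2), sigma = 1)
  expect_equal(got0, -2 + dnorm(log(2), log(2), 1, TRUE))
  # small sigma at the mode approaches the normal normalising constant
  gs <- poisson_lognormal_loglik(0, 1, log(2), M = log(2), sigma = 1e-3)
  expect_equal(gs - (-2), -log(1e-3 * sqrt(2 * pi)), tolerance = 1e-9)
  expect_error(poisson_lognormal_loglik(1.5, 1, 0, 0, 1), "integers")
  expect_error(poisson_lognormal_loglik(1, -1, 0, 0, 1), "positive")
})
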