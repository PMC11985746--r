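# Inference engine: bookkeeping, hard constraints, degenerate cases,
# reproducibility.  Fits here use deliberately small configurations; the
# statistical recovery checks live in the acceptance suite.

fit_small_fertility <- function(samples = 60, warmup = 60, seed = 3,
                                chains = 2) {
  cfg <- small_generator_config()
  tr <- draw_true_parameters(cfg, "fertility")
  tab <- simulate_component_table(tr, cfg, "fertility")
  list(fit = fit_component(default_model_spec("fertility"), tab,
                           mcmc_config(chains = chains, warmup = warmup,
                                       samples = samples, seed = seed)),
       truth = tr, table = tab)
}

test_that("the sampler returns exactly chains x samples draws with diagnostics", {
  res <- fit_small_fertility(samples = 50, warmup = 30)
  fit <- res$fit
  expect_identical(fit$n_draws, 100L)
  expect_identical(nrow(fit$draws), 100L)
  expect_true(all(c("rhat", "ess") %in% names(fit$diagnostics)))
  expect_true(all(is.finite(fit$draws)))
})

test_that("hard constraints hold in every posterior draw", {
  cfg <- small_generator_config()
  tr <- draw_true_parameters(cfg, "internal_migration")
  tab <- simulate_component_table(tr, cfg, "internal_migration")
  fit <- fit_component(default_model_spec("internal_migration"), tab,
                       mcmc_config(chains = 2, warmup = 80, samples = 80,
                                   seed = 5))
  dn <- colnames(fit$draws)
  # first-period kappa is exactly zero
  expect_true(all(fit$draws[, "kappa1[1996]"] == 0))
  expect_true(all(fit$draws[, "kappa2[1996]"] == 0))
  # bilinear loadings sum to one in every draw
  a2 <- fit$draws[, grep("^A2\\[", dn)]
  expect_equal(unname(rowSums(a2)), rep(1, nrow(a2)), tolerance = 1e-10)
  od2 <- fit$draws[, grep("^OD2\\[", dn)]
  expect_equal(unname(rowSums(od2)), rep(1, nrow(od2)), tolerance = 1e-10)
  # symmetric origin-destination prior means: one alpha per unordered pair
  expect_identical(sum(grepl("^alpha\\[", dn)), 3L)
  # autoregressive parameters respect their truncation
  expect_true(all(fit$draws[, "kappa1.phi2"] >= 0 &
                  fit$draws[, "kappa1.phi2"] <= 1))
})

test_that("a no-signal table concentrates the kappa path near zero", {
  reg <- dimension_registry(c("A", "B"), seq(0, 30, 5), 2001:2010,
                            reproductive_window = c(15, 30))
  cells <- expand.grid(origin = c("A", "B"), age = seq(15, 30, 5),
                       year = 2001:2010, stringsAsFactors = FALSE)
  cells$destination <- NA; cells$sex <- NA
  cells$count <- 5000L                      # identical counts, huge exposure
  cells$exposure <- 1e5
  tab <- component_table("fertility", cells, reg)
  fit <- fit_component(default_model_spec("fertility"), tab,
                       mcmc_config(chains = 1, warmup = 150, samples = 150,
                                   seed = 2))
  k <- fit$draws[, paste0("kappa1[", 2002:2010, "]")]
  expect_lt(max(abs(colMeans(k))), 0.05)
})

test_that("identical seed and configuration reproduce identical draws", {
  a <- fit_small_fertility(samples = 40, warmup = 40, seed = 11)
  b <- fit_small_fertility(samples = 40, warmup = 40, seed = 11)
  expect_identical(a$fit$draws, b$fit$draws)
  c <- fit_small_fertility(samples = 40, warmup = 40, seed = 12)
  expect_false(identical(a$fit$draws, c$fit$draws))
})

test_that("component/table mismatches and bad inputs are rejected", {
  cfg <- small_generator_config()
  tr <- draw_true_parameters(cfg, "fertility")
  tab <- simulate_component_table(tr, cfg, "fertility")
  expect_error(fit_component(default_model_spec("mortality"), tab,
                             mcmc_config()), "mortality")
})

test_that("forecasts inherit posterior scale and obey the lognormal median", {
  res <- fit_small_fertility(samples = 80, warmup = 80)
  fc <- forecast_component(res$fit, 2012:2016, seed = 9)
  expect_identical(dim(fc$mu), c(160L, 3L * 7L * 5L))
  expect_true(all(fc$mu > 0))
  # reproducibility under the same seed
  fc2 <- forecast_component(res$fit, 2012:2016, seed = 9)
  expect_identical(fc$mu, fc2$mu)
  # horizon must extend the grid
  expect_error(forecast_component(res$fit, 2014:2016, seed = 1),
               "extend the observed grid")
  # median over draws of exp(M + noise) tracks exp(median M): the forecast
  # median TFR should sit near the fitted-period TFR level (same order)
  tm <- tfr_draws(fc, 2012)
  expect_true(all(is.finite(tm)) && all(tm > 0))
})

test_that("noise-free degenerate forecasts equal the deterministic recursion", {
  res <- fit_small_fertility(samples = 30, warmup = 30, chains = 1)
  fit <- res$fit
  # force a degenerate posterior: single draw, zero innovation and noise
  fit$draws <- fit$draws[1, , drop = FALSE]
  fit$draws[1, "kappa1.sigma"] <- 0
  fit$draws[1, "kappa2.sigma"] <- 0
  fit$draws[1, "sigma"] <- 1e-12
  fit$n_draws <- 1L
  fc <- forecast_component(fit, 2012:2013, seed = 1)
  phi2 <- fit$draws[1, "kappa1.phi2"]
  kT <- fit$draws[1, "kappa1[2011]"]
  expect_equal(unname(fc$kappa_paths[[1]]$kappa1[1, ]),
               unname(c(phi2 * kT, phi2^2 * kT)), tolerance = 1e-10)
})
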