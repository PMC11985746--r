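# Multiregional cohort-component arithmetic.

test_that("identity survivorship proportions give identity transitions", {
  z <- 4
  sbar <- replicate(z, diag(2), simplify = FALSE)
  pbar <- conditional_transitions(sbar)
  for (a in seq_len(z)) expect_equal(pbar[[a]], diag(2))
})

test_that("interior transition matrices are elementwise means of adjacent cohorts", {
  s_x <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  s_xm5 <- matrix(c(0.8, 0.2, 0.4, 0.6), 2, 2, byrow = TRUE)
  pbar <- conditional_transitions(list(s_xm5, s_x, s_x))
  expect_equal(pbar[[2]], (s_x + s_xm5) / 2)
  # youngest group uses the squared approximation
  expect_equal(pbar[[1]], 0.5 * (s_xm5 %*% s_xm5 + s_xm5))
  # open-ended group passes through
  expect_equal(pbar[[3]], s_x)
})

test_that("transition rows stay stochastic and invalid inputs are rejected", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(2:5, 1)
    mk <- function() {
      m <- matrix(runif(n * n), n, n)
      m / rowSums(m)
    }
    sbar <- replicate(6, mk(), simplify = FALSE)
    pbar <- conditional_transitions(sbar)
    for (p in pbar) expect_equal(rowSums(p), rep(1, n), tolerance = 1e-12)
  }
  bad <- list(diag(2), matrix(c(0.5, 0.2, 0.1, 0.9), 2, 2))
  expect_error(conditional_transitions(bad), "sum to 1")
})

test_that("un-conditioning matches the scalar closed form and rejects violations", {
  # zero rates leave transitions untouched
  pbar <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2, byrow = TRUE)
  expect_equal(uncondition(pbar, c(0, 0), c(0, 0)), pbar)
  # single region scalar evaluation
  p1 <- uncondition(matrix(1, 1, 1), 0.02, 0.01)
  expect_equal(drop(p1), (1 - 0.075) / (1 + 0.075))
  # precondition 5/2 (d+e) < 1 enforced, not clipped
  expect_error(uncondition(matrix(1, 1, 1), 0.3, 0.2), "must be < 1")
  # raising any region's mortality weakly decreases all survival diagonals
  d <- c(0.02, 0.03); e <- c(0.01, 0.005)
  base <- uncondition(pbar, d, e)
  bumped <- uncondition(pbar, d + c(0, 0.01), e)
  expect_true(all(bumped <= base + 1e-12))
})

test_that("survivorship matrices follow the interpolation formula", {
  expect_equal(survivorship(diag(2), diag(2)), diag(2))
  s <- survivorship(matrix(0.9), matrix(0.8))
  expect_equal(drop(s), 1.8 * 0.9 / 1.9)
  # one region with equal transitions: S equals P
  expect_equal(drop(survivorship(matrix(0.9), matrix(0.9))), 0.9)
})

test_that("infant survivorship forms agree", {
  expect_equal(infant_survivorship(diag(3)), diag(3))
  # single region: first form with explicit M0
  s1 <- infant_survivorship(matrix(1), M0 = matrix(0.01))
  expect_equal(drop(s1), 1 / 1.025)
  # cross-form consistency: M0 = (2/5)(I-P0)(I+P0)^-1 reproduces form 2
  p0 <- matrix(0.92)
  M0 <- (2 / 5) * (1 - 0.92) / (1 + 0.92)
  expect_equal(infant_survivorship(p0),
               infant_survivorship(p0, M0 = matrix(M0)), tolerance = 1e-12)
})

make_proj_registry <- function(n = 2, regions = c("A", "B")) {
  dimension_registry(regions[seq_len(n)], seq(0, 85, 5), 2011,
                     reproductive_window = c(15, 45))
}

identity_mats <- function(n, z) {
  S <- replicate(z, diag(n), simplify = FALSE)
  m <- list(Pbar = S, P = S, S = S, S_minus5 = diag(n))
  list(m, m)
}

test_that("a closed immortal population without births shifts one group up", {
  reg <- make_proj_registry()
  n <- 2; z <- 18
  K <- array(runif(n * z * 2, 100, 1000), c(n, z, 2))
  G <- array(0, c(n, z, 2))
  f <- matrix(0, n, z)
  out <- project_step(K, identity_mats(n, z), f, G, reg)
  expect_equal(out[, 1, ], array(0, c(n, 2)))
  for (a in 1:(z - 2)) expect_equal(out[, a + 1, ], K[, a, ])
  # open-ended group accumulates survivors of z-1 and z
  expect_equal(out[, z, ], K[, z - 1, ] + K[, z, ])
})

test_that("births split by the sex ratio exactly", {
  reg <- make_proj_registry()
  n <- 2; z <- 18
  K <- array(0, c(n, z, 2))
  K[, 5, 2] <- 1000           # women aged 20-24
  f <- matrix(0, n, z); f[, 5] <- 0.04
  G <- array(0, c(n, z, 2))
  out <- project_step(K, identity_mats(n, z), f, G, reg, srb = 105)
  males <- out[, 1, 1]; females <- out[, 1, 2]
  expect_equal(males / females, rep(105 / 100, n))
  # with identity survivorship total births are 5/2 * f * K
  expect_equal(males + females, rep(2.5 * 0.04 * 1000, n))
})

test_that("zero interregional migration reduces to uniregional projections", {
  reg <- make_proj_registry(3, c("A", "B", "C"))
  n <- 3; z <- 18
  set.seed(9)
  K <- array(runif(n * z * 2, 1000, 5000), c(n, z, 2))
  d <- array(runif(n * z * 2, 0.001, 0.05), c(n, z, 2))
  e <- array(runif(n * z * 2, 0.0005, 0.01), c(n, z, 2))
  f <- matrix(0, n, z); f[, 4:10] <- runif(n * 7, 0.01, 0.08)
  G <- array(runif(n * z * 2, 0, 200), c(n, z, 2))
  sbar <- replicate(z, diag(n), simplify = FALSE)    # no migration
  mats <- list(make_matrix_set(sbar, d[, , 1], e[, , 1]),
               make_matrix_set(sbar, d[, , 2], e[, , 2]))
  out <- project_step(K, mats, f, G, reg)
  for (r in 1:n) {
    oracle <- uniregional_oracle_step(
      K = rbind(K[r, , 1], K[r, , 2]),
      d = rbind(d[r, , 1], d[r, , 2]),
      e = rbind(e[r, , 1], e[r, , 2]),
      f = f[r, ],
      G = rbind(G[r, , 1], G[r, , 2]),
      alpha_idx = 4, beta_idx = 10)
    expect_equal(out[r, , 1], oracle[1, ], tolerance = 1e-12)
    expect_equal(out[r, , 2], oracle[2, ], tolerance = 1e-12)
  }
})

test_that("matrix orientation: rows are origins", {
  reg <- make_proj_registry()
  n <- 2; z <- 18
  # everyone in A moves to B; B never moves
  move <- matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE)
  sbar <- replicate(z, move, simplify = FALSE)
  d <- matrix(0, n, z); e <- matrix(0, n, z)
  mats_one <- make_matrix_set(sbar, d, e)
  K <- array(0, c(n, z, 2)); K[1, 3, ] <- 100   # A only, age 10-14
  out <- project_step(K, list(mats_one, mats_one), matrix(0, n, z),
                      array(0, c(n, z, 2)), reg)
  expect_equal(out[2, 4, 1], 100)   # arrived in B, aged one group
  expect_equal(out[1, 4, 1], 0)
})

test_that("raising a region's mortality does not increase its survivors", {
  reg <- make_proj_registry()
  n <- 2; z <- 18
  set.seed(10)
  K <- array(1000, c(n, z, 2))
  mk <- function() {
    m <- matrix(c(0.95, 0.05, 0.1, 0.9), 2, 2, byrow = TRUE)
    replicate(z, m, simplify = FALSE)
  }
  d0 <- matrix(0.01, n, z); e0 <- matrix(0.002, n, z)
  f0 <- matrix(0, n, z)
  G0 <- array(0, c(n, z, 2))
  base <- project_step(K, list(make_matrix_set(mk(), d0, e0),
                               make_matrix_set(mk(), d0, e0)), f0, G0, reg)
  d1 <- d0; d1[1, ] <- 0.05
  high <- project_step(K, list(make_matrix_set(mk(), d1, e0),
                               make_matrix_set(mk(), d1, e0)), f0, G0, reg)
  expect_true(all(high[1, -1, ] <= base[1, -1, ] + 1e-9))
})

test_that("project_horizon composes project_step and excludes invalid draws", {
  cfg <- small_generator_config()
  fx <- make_full_fixture(cfg)
  reg <- fx$baseline$registry
  # build degenerate one-draw forecasts directly from plausible constants
  mk_fc <- function(component, years, value) {
    reg_f <- registry_with_years(reg, years)
    cells <- mrpop:::component_cell_grid(component, reg_f)
    structure(list(component = component, cells = cells,
                   mu = matrix(value, 1, nrow(cells)), years = years,
                   registry = reg_f, base_registry = reg,
                   kappa_paths = NULL, draw_index = 1L),
              class = "mrpop_forecast")
  }
  years_a <- 2012:2021
  fcs <- list(
    internal_migration = mk_fc("internal_migration", c(2016, 2021), 0.01),
    mortality = mk_fc("mortality", years_a, 0.01),
    fertility = mk_fc("fertility", years_a, 0.05),
    immigration = mk_fc("immigration", years_a, 500),
    emigration = mk_fc("emigration", years_a, 0.002))
  pf <- project_horizon(fx$baseline, fcs, steps = 2)
  expect_identical(dim(pf$population)[1], 1L)
  expect_identical(length(pf$excluded_draws), 0L)
  # one-step equality with a direct project_step call
  sbar <- mrpop:::sbar_from_migration(fcs$internal_migration$mu[1, ],
                                      fcs$internal_migration$registry, 2016)
  d <- mrpop:::interval_rates(fcs$mortality$mu[1, ], fcs$mortality$registry,
                              2012:2016, "mortality", mean)
  e <- mrpop:::interval_rates(fcs$emigration$mu[1, ], fcs$emigration$registry,
                              2012:2016, "emigration", mean)
  f <- mrpop:::interval_rates(fcs$fertility$mu[1, ], fcs$fertility$registry,
                              2012:2016, "fertility", mean)
  G <- mrpop:::interval_rates(fcs$immigration$mu[1, ], fcs$immigration$registry,
                              2012:2016, "immigration", sum)
  mats <- list(mrpop:::make_matrix_set(sbar[[1]], d[, , 1], e[, , 1]),
               mrpop:::make_matrix_set(sbar[[2]], d[, , 2], e[, , 2]))
  direct <- project_step(fx$baseline$values, mats, f, G, reg)
  expect_equal(pf$population[1, , , , 2], direct, tolerance = 1e-12,
               ignore_attr = TRUE)
  # a draw violating the un-conditioning precondition is excluded
  bad <- fcs
  bad$mortality <- mk_fc("mortality", years_a, 0.5)
  pf_bad <- project_horizon(fx$baseline, bad, steps = 1)
  expect_identical(pf_bad$excluded_draws, 1L)
  expect_identical(dim(pf_bad$population)[1], 0L)
})
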