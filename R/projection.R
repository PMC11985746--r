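# Multiregional cohort-component arithmetic: conditional transition
# matrices, un-conditioning for mortality and emigration, survivorship
# matrices, and the five-year projection step.  All matrices are n x n with
# rows indexing origin regions and columns destinations; populations are
# stacked as region vectors per age group and sex.

check_stochastic_rows <- function(m, what) {
  if (any(m < -1e-12))
    stop_mrpop("%s has negative entries", what)
  if (any(abs(rowSums(m) - 1) > 1e-8))
    stop_mrpop("%s rows must sum to 1", what)
}

#' Conditional transition probability matrices from survivorship proportions
#'
#' Averages adjacent conditional survivorship proportion matrices to exact
#' ages: `Pbar_x = (Sbar_x + Sbar_{x-5}) / 2` for interior ages, the
#' squared approximation `Pbar_0 = ((Sbar_0)^2 + Sbar_0) / 2` for the
#' youngest group, and `Pbar_z = Sbar_z` for the open-ended group.
#'
#' @param sbar list of `n x n` row-stochastic matrices, one per age group in
#'   ascending age order (first entry age 0-4, last the open-ended group);
#'   `sbar[[a]]` is the matrix for the cohort aged in group `a` at the start
#'   of the interval.
#' @return list of conditional transition matrices `Pbar`, same indexing.
#' @export
conditional_transitions <- function(sbar) {
  z <- length(sbar)
  stopifnot(z >= 2)
  for (a in seq_len(z)) check_stochastic_rows(sbar[[a]], sprintf("Sbar[%d]", a))
  pbar <- vector("list", z)
  pbar[[1]] <- 0.5 * (sbar[[1]] %*% sbar[[1]] + sbar[[1]])
  if (z > 2)
    for (a in 2:(z - 1)) pbar[[a]] <- 0.5 * (sbar[[a]] + sbar[[a - 1]])
  pbar[[z]] <- sbar[[z]]
  names(pbar) <- names(sbar)
  pbar
}

#' Un-condition transition probabilities for mortality and emigration
#'
#' Builds the diagonal adjustment `P^DE` with entries
#' `(1 - 5/2 (d_r + e_r)) / (1 + 5/2 sum_k Pbar_rk (d_k + e_k))` and returns
#' `P = Pbar %*% P^DE`.  Requires `5/2 (d_r + e_r) < 1` for every region;
#' a violation raises an error rather than being clipped.
#'
#' @param pbar conditional transition matrix (`n x n`, row-stochastic).
#' @param d,e annualised region mortality and emigration rates (length `n`).
#' @return unconditioned transition probability matrix `P`.
#' @export
uncondition <- function(pbar, d, e) {
  n <- nrow(pbar)
  stopifnot(length(d) == n, length(e) == n)
  if (any(d < 0) || any(e < 0)) stop_mrpop("rates must be non-negative")
  load <- 2.5 * (d + e)
  if (any(load >= 1))
    stop_mrpop("5/2 (d + e) must be < 1 for every region (got max %.3f)",
               max(load))
  denom <- 1 + drop(pbar %*% load)
  pde <- diag((1 - load) / denom, nrow = n)
  pbar %*% pde
}

#' Survivorship matrix for one age group
#'
#' `S_x = (I + P_{x+5}) P_x (I + P_x)^{-1}`.
#'
#' @param p_x,p_x5 unconditioned transition matrices at ages `x` and `x+5`.
#' @return survivorship matrix advancing the age-`x` population five years.
#' @export
survivorship <- function(p_x, p_x5) {
  n <- nrow(p_x)
  I <- diag(n)
  (I + p_x5) %*% p_x %*% solve(I + p_x)
}

#' Infant survivorship matrix
#'
#' `S_{-5} = [I + (I + P_0)^{-1} (I - P_0)]^{-1}`, the survivorship applied
#' to births of the projection interval; equivalently `(I + 5/2 M_0)^{-1}`
#' when an explicit matrix `M_0` of first-age-group mortality rates is
#' supplied.
#'
#' @param p0 unconditioned transition matrix for the first age group.
#' @param M0 optional explicit mortality-rate matrix; when given, the first
#'   form is evaluated instead.
#' @return infant survivorship matrix.
#' @export
infant_survivorship <- function(p0, M0 = NULL) {
  n <- nrow(p0)
  I <- diag(n)
  if (!is.null(M0)) return(solve(I + 2.5 * M0))
  solve(I + solve(I + p0) %*% (I - p0))
}

# Full matrix set for one sex: conditional transitions, unconditioned
# probabilities, survivorship per age, and infant survivorship.
make_matrix_set <- function(sbar, d, e) {
  z <- length(sbar)
  pbar <- conditional_transitions(sbar)
  p <- lapply(seq_len(z), function(a) uncondition(pbar[[a]], d[, a], e[, a]))
  S <- vector("list", z)
  for (a in seq_len(z)) {
    p_next <- if (a < z) p[[a + 1]] else p[[z]]   # open group: P_{z+5} := P_z
    S[[a]] <- survivorship(p[[a]], p_next)
  }
  list(Pbar = pbar, P = p, S = S, S_minus5 = infant_survivorship(p[[1]]))
}

#' One five-year multiregional cohort-component step
#'
#' Advances a region x age x sex population array one projection interval:
#' existing cohorts age through their survivorship matrices with half the
#' period's immigrants added before and half after survival, the open-ended
#' group accumulates survivors of the two oldest cohorts, and births are
#' generated from female exposure, survived with the infant survivorship
#' matrix and split by the sex ratio at birth.
#'
#' @param K region x age x sex population array at time `t`.
#' @param mats named list `list(M = , F = )` of matrix sets built by the
#'   engine (per-sex survivorship, infant survivorship).
#' @param f region x age matrix of annualised fertility rates (zero outside
#'   the reproductive window).
#' @param G region x age x sex array of immigrant counts for the interval.
#' @param registry the [dimension_registry()].
#' @param srb sex ratio at birth (males per 100 females), default 105.
#' @return region x age x sex population array at `t + 5`.
#' @export
project_step <- function(K, mats, f, G, registry, srb = 105) {
  n <- n_regions(registry); z <- n_ages(registry)
  stopifnot(all(dim(K) == c(n, z, 2)), all(dim(G) == c(n, z, 2)),
            all(dim(f) == c(n, z)))
  win <- registry$reproductive_window
  if (any(f[, -(win[1]:win[2])] != 0))
    stop_mrpop("fertility rates must be zero outside the reproductive window")
  # matrices are row-origin (rows = origin, columns = destination), so a
  # column population vector advances as t(S) %*% K (equivalently, K as a
  # row vector times S)
  newK <- array(0, c(n, z, 2), dimnames = dimnames(K))
  for (s in 1:2) {
    ms <- mats[[s]]
    half_in <- K[, , s] + G[, , s] / 2
    for (a in seq_len(z - 1))
      newK[, a + 1, s] <- drop(crossprod(ms$S[[a]], half_in[, a])) +
        G[, a + 1, s] / 2
    newK[, z, s] <- newK[, z, s] + drop(crossprod(ms$S[[z]], half_in[, z]))
  }
  # births from female exposure: mothers age-and-migrate, then bear at the
  # rates of the region where the birth occurs; newborns migrate via S_{-5}
  mf <- mats[[2]]
  sum_term <- numeric(n)
  for (a in win[1]:win[2]) {
    fnext <- if (a + 1 <= z) f[, a + 1] else numeric(n)
    expo <- K[, a, 2] + G[, a, 2] / 2
    sum_term <- sum_term + f[, a] * expo +
      fnext * drop(crossprod(mf$S[[a]], expo))
  }
  births <- 2.5 * sum_term
  share_m <- srb / (100 + srb)
  newK[, 1, 1] <- drop(crossprod(mats[[1]]$S_minus5, births * share_m)) +
    G[, 1, 1] / 2
  newK[, 1, 2] <- drop(crossprod(mats[[2]]$S_minus5, births * (1 - share_m))) +
    G[, 1, 2] / 2
  if (any(newK < 0))
    stop_mrpop("projection produced negative population; invalid rate inputs")
  newK
}

# ---- assembling projection inputs from rate forecasts -----------------------

# Conditional survivorship matrices per sex from a migration forecast draw.
# mu_mig is the draw's vector over the canonical migration grid.  Migration
# probabilities are recorded at terminal age; the matrix for the cohort in
# start-age group a uses terminal-age group a+1, and the open-ended group
# reuses the terminal open-ended matrix.
sbar_from_migration <- function(mu_vec, reg_f, year) {
  n <- length(reg_f$regions); z <- n_ages(reg_f)
  cells <- component_cell_grid("internal_migration", reg_f)
  sel <- cells$year == year
  full <- array(NA_real_, c(n, n, z, 2))
  oi <- match(cells$origin[sel], reg_f$regions)
  di <- match(cells$destination[sel], reg_f$regions)
  ai <- match(cells$age[sel], reg_f$age_groups)
  si <- match(cells$sex[sel], reg_f$sexes)
  full[cbind(oi, di, ai, si)] <- mu_vec[sel]
  out <- list()
  for (s in 1:2) {
    sb <- vector("list", z)
    for (a in seq_len(z)) {
      term_a <- min(a + 1L, z)      # terminal-age group observing cohort a
      m <- full[, , term_a, s]
      diag(m) <- 0
      rs <- rowSums(m)
      if (any(rs >= 1))
        stop_mrpop("out-migration probabilities sum to >= 1 for a region")
      diag(m) <- 1 - rs
      sb[[a]] <- m
    }
    out[[s]] <- sb
  }
  names(out) <- reg_f$sexes
  out
}

# Mean annual rates (or summed counts) over the interval (t, t+5] from an
# annual forecast draw vector on the canonical grid.
interval_rates <- function(mu_vec, reg_f, years_in, component, aggregate) {
  n <- length(reg_f$regions); z_full <- n_ages(reg_f)
  if (component == "fertility") {
    ages <- reproductive_ages(reg_f)
    arr <- array(mu_vec, c(n, length(ages), n_years(reg_f)))
    ti <- match(years_in, reg_f$years)
    sub <- arr[, , ti, drop = FALSE]
    agg <- apply(sub, c(1, 2), aggregate)
    out <- matrix(0, n, z_full)
    out[, match(ages, reg_f$age_groups)] <- agg
    return(out)
  }
  arr <- array(mu_vec, c(n, z_full, 2, n_years(reg_f)))
  ti <- match(years_in, reg_f$years)
  sub <- arr[, , , ti, drop = FALSE]
  apply(sub, c(1, 2, 3), aggregate)
}

#' Project the population forward over posterior draws
#'
#' Per posterior draw: builds conditional survivorship matrices from the
#' migration forecast, averages the five forecasted annual mortality,
#' emigration and fertility rates of each interval (immigrant counts are
#' summed), constructs the per-sex survivorship matrices, and iterates
#' [project_step()].  Draws whose rates violate the un-conditioning
#' precondition `5/2 (d + e) < 1` or whose out-migration probabilities sum
#' past one are excluded with a recorded count.
#'
#' @param baseline a [baseline_population()] at the jump-off year.
#' @param forecasts named list with elements `internal_migration`,
#'   `mortality`, `fertility`, `immigration`, `emigration`, each an
#'   `mrpop_forecast` covering the horizon (annual components annually,
#'   migration quinquennially).
#' @param steps number of five-year projection intervals.
#' @param srb sex ratio at birth (males per 100 females).
#' @return an object of class `mrpop_popforecast`: array
#'   `draw x region x age x sex x year` (including the baseline year) plus
#'   the indices of excluded draws.
#' @export
project_horizon <- function(baseline, forecasts, steps, srb = 105) {
  stopifnot(inherits(baseline, "mrpop_baseline"))
  need <- c("internal_migration", "mortality", "fertility", "immigration",
            "emigration")
  if (!all(need %in% names(forecasts)))
    stop_mrpop("forecasts must contain: %s", paste(need, collapse = ", "))
  reg <- baseline$registry
  t0 <- baseline$year
  B <- min(vapply(forecasts[need], function(f) nrow(f$mu), 0L))
  years_out <- t0 + 5L * (0:steps)
  pop <- array(NA_real_, c(B, n_regions(reg), n_ages(reg), 2, steps + 1),
               dimnames = list(NULL, reg$regions, reg$age_groups, reg$sexes,
                               years_out))
  excluded <- integer()
  for (b in seq_len(B)) {
    K <- baseline$values
    pop[b, , , , 1] <- K
    ok <- TRUE
    for (st in seq_len(steps)) {
      res <- tryCatch({
        yr_end <- t0 + 5L * st
        yrs_in <- (yr_end - 4L):yr_end
        sbar <- sbar_from_migration(forecasts$internal_migration$mu[b, ],
                                    forecasts$internal_migration$registry,
                                    yr_end)
        d <- interval_rates(forecasts$mortality$mu[b, ],
                            forecasts$mortality$registry, yrs_in,
                            "mortality", mean)
        e <- interval_rates(forecasts$emigration$mu[b, ],
                            forecasts$emigration$registry, yrs_in,
                            "emigration", mean)
        f <- interval_rates(forecasts$fertility$mu[b, ],
                            forecasts$fertility$registry, yrs_in,
                            "fertility", mean)
        G <- interval_rates(forecasts$immigration$mu[b, ],
                            forecasts$immigration$registry, yrs_in,
                            "immigration", sum)
        mats <- list(make_matrix_set(sbar[[1]], d[, , 1], e[, , 1]),
                     make_matrix_set(sbar[[2]], d[, , 2], e[, , 2]))
        project_step(K, mats, f, G, reg, srb = srb)
      }, error = function(err) err)
      if (inherits(res, "error")) {
        ok <- FALSE
        break
      }
      K <- res
      pop[b, , , , st + 1] <- K
    }
    if (!ok) excluded <- c(excluded, b)
  }
  if (length(excluded)) pop <- pop[-excluded, , , , , drop = FALSE]
  structure(list(population = pop, years = years_out, registry = reg,
                 baseline_year = t0, srb = srb, excluded_draws = excluded),
            class = "mrpop_popforecast")
}

#' @export
print.mrpop_popforecast <- function(x, ...) {
  cat("<mrpop_popforecast>", dim(x$population)[1], "draws,",
      paste(range(x$years), collapse = "-"), "\n")
  if (length(x$excluded_draws))
    cat("  excluded draws (precondition violations):",
        length(x$excluded_draws), "\n")
  invisible(x)
}

#' Persist a population forecast as long CSV with a quantile summary
#'
#' @param pf an `mrpop_popforecast`.
#' @param path draw-level CSV path.
#' @param summary_path optional quantile-summary CSV path.
#' @export
write_popforecast <- function(pf, path, summary_path = NULL) {
  dd <- dim(pf$population)
  grid <- expand.grid(draw = seq_len(dd[1]), region = pf$registry$regions,
                      age = pf$registry$age_groups, sex = pf$registry$sexes,
                      year = pf$years, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$population <- as.vector(pf$population)
  utils::write.csv(grid, path, row.names = FALSE, quote = FALSE)
  if (!is.null(summary_path)) {
    qs <- apply(pf$population, c(2, 3, 4, 5), mrpop_quantile,
                probs = c(0.025, 0.1, 0.25, 0.5, 0.75, 0.9, 0.975))
    sgrid <- expand.grid(region = pf$registry$regions,
                         age = pf$registry$age_groups, sex = pf$registry$sexes,
                         year = pf$years, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
    qm <- matrix(aperm(qs, c(2, 3, 4, 5, 1)), nrow = nrow(sgrid))
    colnames(qm) <- paste0("q", c(2.5, 10, 25, 50, 75, 90, 97.5))
    utils::write.csv(cbind(sgrid, qm), summary_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}
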