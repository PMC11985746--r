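# Synthetic-data generator: builds complete, internally consistent inputs
# for all five demographic components from known ("true") parameters, so
# every module is testable without external downloads and so parameter
# recovery can be scored against the generative truth.

#' Generator configuration
#'
#' Defaults mirror the reference application shape: 8 regions, 18 five-year
#' age groups (0-4 ... 85+), annual vital series 1981-2011, quinquennial
#' migration series 1986-2011 (six observations) and an international-
#' migration definition break at 2004.  Baseline regional populations follow
#' a smooth age pyramid (declining exponential with a young-adult hump) with
#' heterogeneous region sizes; they are synthetic and fit to no real data.
#'
#' @param seed RNG seed controlling every generated truth and count.
#' @param regions region codes.
#' @param age_groups age-group lower bounds.
#' @param vital_years annual years for mortality/fertility/international
#'   migration.
#' @param migration_years quinquennial internal-migration observation years
#'   (each needs a population five years earlier for exposures).
#' @param break_year definition-change year for international migration.
#' @param region_pop baseline total population per region (persons).
#' @param growth annual population growth rate used for exposures.
#' @param truth_overrides named list of per-component overrides for the true
#'   parameters (matched by name into the generated truth list).
#' @return a `GeneratorConfig`-style list.
#' @export
generator_config <- function(seed = 1,
                             regions = c("NSW", "VIC", "QLD", "SA", "WA",
                                         "TAS", "NT", "ACT"),
                             age_groups = seq(0, 85, by = 5),
                             vital_years = 1981:2011,
                             migration_years = seq(1986, 2011, by = 5),
                             break_year = 2004,
                             region_pop = NULL,
                             growth = 0.012,
                             truth_overrides = list()) {
  if (is.null(region_pop)) {
    base <- c(7.2e6, 5.9e6, 4.6e6, 1.7e6, 2.6e6, 5.1e5, 2.4e5, 3.9e5)
    region_pop <- rep_len(base, length(regions))
  }
  stopifnot(length(region_pop) == length(regions))
  list(seed = as.integer(seed), regions = as.character(regions),
       age_groups = as.integer(age_groups),
       vital_years = as.integer(vital_years),
       migration_years = as.integer(migration_years),
       break_year = as.integer(break_year),
       region_pop = region_pop, growth = growth,
       truth_overrides = truth_overrides)
}

# Smooth synthetic age structure: declining exponential plus a young-adult
# hump, normalised to 1.
synthetic_age_structure <- function(age_groups) {
  mid <- age_groups + 2.5
  w <- exp(-0.018 * mid) * (1 + 0.35 * exp(-((mid - 27) / 12)^2))
  w / sum(w)
}

# Population array region x age x sex x year used for exposures.
synthetic_population <- function(cfg, years) {
  ages <- cfg$age_groups
  w <- synthetic_age_structure(ages)
  y0 <- min(years)
  arr <- array(0, c(length(cfg$regions), length(ages), 2, length(years)),
               dimnames = list(cfg$regions, ages, c("M", "F"), years))
  for (yi in seq_along(years)) {
    fac <- (1 + cfg$growth)^(years[yi] - y0)
    for (r in seq_along(cfg$regions))
      arr[r, , , yi] <- cfg$region_pop[r] * fac * w / 2
  }
  arr
}

# Plausible log age profiles, centred to mean zero over the used age range.
# Mortality: Gompertz-type rise with an infant bump; fertility: log-quadratic
# hump around the late twenties; migration components: young-adult hump.
age_profile_log <- function(component, age_mids) {
  switch(component,
    mortality = log(2.5e-4) + 0.085 * pmax(age_mids - 10, 0) +
      2.2 * (age_mids < 5),
    fertility = log(0.11) - ((age_mids - 27) / 8)^2,
    # migration-type components: bounded young-adult bump on the log scale
    1.5 * exp(-((age_mids - 22) / 15)^2))
}

component_registry <- function(cfg, component) {
  years <- if (component == "internal_migration") cfg$migration_years
           else cfg$vital_years
  dimension_registry(cfg$regions, cfg$age_groups, years)
}

tspec_dims <- function(spec, name) {
  for (tm in spec$terms) if (tm$name == name) return(tm$dims)
  character()
}

# RNG substream offsets so each component's truth is reproducible in
# isolation.
component_seed <- function(cfg, component) {
  cfg$seed + 1000L * match(component, COMPONENTS)
}

#' Draw the true generative parameters for one component
#'
#' Produces a complete parameter set for the component's default model
#' specification: intercept pinned at a demographically plausible level,
#' effects drawn from their (fixed-scale) priors, bilinear loadings drawn
#' from the constrained prior (summing to one by construction), kappa paths
#' simulated from the declared dynamics with the first period fixed at zero,
#' and symmetric origin-destination means for internal migration.
#'
#' @param cfg a [generator_config()].
#' @param component component name.
#' @return list with `params`, `kappa_values`, `dynamics`, `sigma` usable by
#'   [linear_predictor()].
#' @export
draw_true_parameters <- function(cfg, component) {
  component <- match.arg(component, COMPONENTS)
  set.seed(component_seed(cfg, component))
  reg <- component_registry(cfg, component)
  spec <- default_model_spec(component, break_year = cfg$break_year)
  grid1 <- component_cell_grid(component, reg)[1, , drop = FALSE]
  frame <- build_frame(spec, grid1, reg)
  ages_used <- if (component == "fertility") reproductive_ages(reg)
               else reg$age_groups
  prof <- age_profile_log(component, ages_used + 2.5)
  # mortality and fertility take their overall level from the age schedule;
  # the count/probability components use a fixed plausible intercept
  intercepts <- c(internal_migration = log(0.01),
                  mortality = mean(prof),
                  fertility = mean(prof),
                  immigration = log(1500),
                  emigration = log(0.004))
  prof_c <- prof - mean(prof)
  sex_shift <- if (component == "mortality") c(0.2, -0.2) else c(0, 0)
  main_sd <- 0.3
  params <- list()
  for (tm in frame$terms) {
    if (tm$kind == "intercept") {
      params[[tm$name]] <- unname(intercepts[component])
    } else if (tm$name %in% c("A1", "AS1") && "age" %in% tspec_dims(spec, tm$name)) {
      # realistic age schedule plus idiosyncratic noise
      per_sex <- length(tspec_dims(spec, tm$name)) == 2
      base <- if (per_sex) c(prof_c + sex_shift[1], prof_c + sex_shift[2])
              else prof_c
      params[[tm$name]] <- base + stats::rnorm(tm$L, 0, 0.15)
    } else if (tm$kind == "bilinear_loading") {
      L <- tm$L
      Sig <- solve(bilinear_prior_precision(L))
      R <- chol(Sig)
      m <- matrix(NA_real_, tm$n_groups, L)
      for (g in seq_len(tm$n_groups)) {
        u <- 1 / L + drop(t(R) %*% stats::rnorm(L - 1))
        m[g, ] <- constrain_bilinear_loadings(u)
      }
      params[[tm$name]] <- m
    } else if (tm$prior$family == "normal_fixed_sd") {
      params[[tm$name]] <- stats::rnorm(tm$L, tm$prior$mean, tm$prior$sd)
    } else if (tm$prior$family == "symmetric_od_normal") {
      alpha <- stats::rnorm(nrow(unordered_pairs(reg$regions)), 0, 0.4)
      mu <- alpha[od_to_unordered(reg$regions)]
      params[[tm$name]] <- stats::rnorm(tm$L, mu, 0.15)
      params[[paste0(".alpha_", tm$name)]] <- alpha
    } else {
      params[[tm$name]] <- stats::rnorm(tm$L, 0, main_sd)
    }
  }
  dynamics <- list()
  kappa_values <- list()
  T <- n_years(reg)
  for (ks in spec$kappas) {
    if (ks$sex_paired) {
      dyn <- list(phi1 = if (component == "mortality") c(-0.25, -0.22)
                         else c(0.05, 0.04),
                  phi2 = if (ks$dynamics == "var1_drift") c(0.6, 0.6)
                         else c(1, 1),
                  sigma_M = 0.08, sigma_F = 0.08, rho = 0.8)
      Sigma <- cov_from_corr(matrix(c(1, dyn$rho, dyn$rho, 1), 2, 2),
                             c(dyn$sigma_M, dyn$sigma_F))
      Lc <- t(chol(Sigma))
      kap <- matrix(0, 2, T)
      for (t in 2:T)
        kap[, t] <- dyn$phi1 + dyn$phi2 * kap[, t - 1] +
          drop(Lc %*% stats::rnorm(2))
      dynamics[[ks$name]] <- dyn
      kappa_values[[ks$name]] <- kap
    } else {
      dyn <- list(phi1 = if (kappa_has_drift(ks) &&
                             ks$dynamics != "ar1_nodrift") 0.05 else 0,
                  phi2 = switch(ks$dynamics, rw_drift = 1, 0.6),
                  sigma = if (reg$year_step == 5) 0.15 else 0.08)
      kap <- numeric(T)
      for (t in 2:T)
        kap[t] <- dyn$phi1 + dyn$phi2 * kap[t - 1] +
          stats::rnorm(1, 0, dyn$sigma)
      dynamics[[ks$name]] <- dyn
      kappa_values[[ks$name]] <- kap
    }
  }
  truth <- list(params = params, kappa_values = kappa_values,
                dynamics = dynamics, sigma = 0.08)
  truth <- calibrate_truth_level(truth, cfg, component, spec, reg)
  ov <- cfg$truth_overrides[[component]]
  if (!is.null(ov)) truth <- utils::modifyList(truth, ov)
  truth
}

# Keep the generated system inside the projection model's domain: the
# multistate un-conditioning requires 5/2 (d + e) < 1 in every region and
# out-migration probabilities must sum below one.  The worst-case truth rate
# is evaluated over the observed span plus a drift-extended three-interval
# forecast horizon; if it breaches the cap the component's overall level
# (intercept) is scaled down.  Real demographic systems sit far inside
# these caps; this guards the stylised tails of the generator.
calibrate_truth_level <- function(truth, cfg, component, spec, reg) {
  caps <- c(mortality = 0.28, emigration = 0.06, internal_migration = 0.8)
  if (!component %in% names(caps)) return(truth)
  horizon <- if (reg$year_step == 5) 3L else 15L
  kv_ext <- truth$kappa_values
  yrs_ext <- c(reg$years, max(reg$years) + reg$year_step * seq_len(horizon))
  for (kn in names(kv_ext)) {
    kv <- kv_ext[[kn]]
    dyn <- truth$dynamics[[kn]]
    if (is.matrix(kv)) {
      ext <- matrix(NA_real_, 2, horizon)
      prev <- kv[, ncol(kv)]
      for (h in seq_len(horizon)) {
        prev <- dyn$phi1 + dyn$phi2 * prev
        ext[, h] <- prev
      }
      kv_ext[[kn]] <- cbind(kv, ext)
    } else {
      ext <- numeric(horizon)
      prev <- kv[length(kv)]
      for (h in seq_len(horizon)) {
        prev <- dyn$phi1 + dyn$phi2 * prev
        ext[h] <- prev
      }
      kv_ext[[kn]] <- c(kv, ext)
    }
  }
  reg_ext <- dimension_registry(reg$regions, reg$age_groups, yrs_ext,
                                reg$age_groups[reg$reproductive_window],
                                reg$sexes)
  cells <- component_cell_grid(component, reg_ext)
  M <- linear_predictor(spec, truth$params, kv_ext, cells, reg_ext)
  worst <- if (component == "internal_migration") {
    max(tapply(exp(M), paste(cells$origin, cells$age, cells$sex, cells$year),
               sum))
  } else max(exp(M))
  # allowance for overdispersion noise and posterior spread
  worst <- worst * exp(3 * truth$sigma)
  if (worst > caps[component])
    truth$params$c <- truth$params$c - log(worst / caps[component])
  truth
}

#' Simulate a component table from true parameters
#'
#' Per cell: evaluates the log-bilinear predictor, draws the latent log rate
#' `log mu ~ N(M, sigma^2)` and the count `Y ~ Poisson(mu * K)`.
#'
#' @param truth output of [draw_true_parameters()].
#' @param cfg a [generator_config()].
#' @param component component name.
#' @param exposures data frame matching the component grid with an
#'   `exposure` column, or `NULL` to build the synthetic population
#'   exposures internally.
#' @return a validated [component_table()].
#' @export
simulate_component_table <- function(truth, cfg, component, exposures = NULL) {
  component <- match.arg(component, COMPONENTS)
  reg <- component_registry(cfg, component)
  cells <- component_cell_grid(component, reg)
  if (is.null(exposures)) {
    cells$exposure <- synthetic_exposure(cfg, component, cells)
  } else {
    key_e <- paste(exposures$origin, exposures$age,
                   exposures$sex %||% "", exposures$year)
    key_c <- paste(cells$origin, cells$age,
                   ifelse(is.na(cells$sex), "", cells$sex), cells$year)
    cells$exposure <- exposures$exposure[match(key_c, key_e)]
  }
  spec <- default_model_spec(component, break_year = cfg$break_year)
  M <- linear_predictor(spec, truth$params, truth$kappa_values, cells, reg)
  set.seed(component_seed(cfg, component) + 1L)
  log_mu <- M + stats::rnorm(nrow(cells), 0, truth$sigma)
  cells$count <- stats::rpois(nrow(cells), exp(log_mu) * cells$exposure)
  component_table(component, cells, reg)
}

# Exposure column for a component grid from the synthetic population.
synthetic_exposure <- function(cfg, component, cells) {
  if (component == "immigration") return(rep(1, nrow(cells)))
  if (component == "internal_migration") {
    years_needed <- sort(unique(c(cfg$vital_years,
                                  cfg$migration_years - 5L)))
    pops <- synthetic_population(cfg, years_needed)
    reg <- component_registry(cfg, component)
    ex <- lag_exposure_for_migration(pops, reg)
    key_e <- paste(ex$origin, ex$age, ex$sex, ex$year)
    key_c <- paste(cells$origin, cells$age, cells$sex, cells$year)
    return(ex$exposure[match(key_c, key_e)])
  }
  pops <- synthetic_population(cfg, cfg$vital_years)
  ai <- match(cells$age, cfg$age_groups)
  yi <- match(cells$year, cfg$vital_years)
  si <- if (component == "fertility") rep(2L, nrow(cells))
        else match(cells$sex, c("M", "F"))
  ri <- match(cells$origin, cfg$regions)
  pops[cbind(ri, ai, si, yi)]
}

#' Generate the full five-component synthetic fixture
#'
#' Builds a coherent system: one table per component (with exposures drawn
#' from a shared synthetic population so components are internally
#' consistent), the baseline population at the final vital year, and the
#' truth bundle for parameter-recovery scoring.  Bit-identical given the
#' seed.
#'
#' @param cfg a [generator_config()].
#' @return list with `tables` (named list of [component_table()]s),
#'   `baseline` ([baseline_population()]), `truths` (per-component truth
#'   lists) and `config`.
#' @export
make_full_fixture <- function(cfg = generator_config()) {
  truths <- stats::setNames(
    lapply(COMPONENTS, function(cp) draw_true_parameters(cfg, cp)),
    COMPONENTS)
  tables <- stats::setNames(
    lapply(COMPONENTS, function(cp)
      simulate_component_table(truths[[cp]], cfg, cp)),
    COMPONENTS)
  t0 <- max(cfg$vital_years)
  pops <- synthetic_population(cfg, t0)
  baseline <- baseline_population(
    array(pops, dim(pops)[1:3]),
    component_registry(cfg, "mortality"), t0)
  list(tables = tables, baseline = baseline, truths = truths, config = cfg)
}

#' Write a full fixture to a directory of CSV/YAML files
#'
#' @param fixture output of [make_full_fixture()].
#' @param dir directory.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cp in names(fixture$tables))
    write_component_table(fixture$tables[[cp]], file.path(dir, paste0(cp, ".csv")))
  b <- fixture$baseline
  grid <- expand.grid(region = b$registry$regions, age = b$registry$age_groups,
                      sex = b$registry$sexes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$population <- as.vector(b$values)
  utils::write.csv(cbind(year = b$year, grid),
                   file.path(dir, "baseline.csv"), row.names = FALSE,
                   quote = FALSE)
  yaml::write_yaml(list(seed = fixture$config$seed,
                        regions = fixture$config$regions,
                        age_groups = fixture$config$age_groups,
                        vital_years = range(fixture$config$vital_years),
                        migration_years = fixture$config$migration_years,
                        break_year = fixture$config$break_year),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
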