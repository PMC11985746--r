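# End-to-end orchestration: staged fit / forecast / project commands that
# communicate through files, so each stage is independently re-runnable.
# All randomness flows from the single run-config seed via fixed
# per-component offsets.

#' Read and validate a pipeline run configuration
#'
#' The YAML configuration names the input tables and baseline, the shared
#' dimension registry, MCMC settings, the forecast horizon and the output
#' directory:
#' ```yaml
#' regions: [NSW, VIC, ...]
#' age_groups: [0, 5, ..., 85]
#' vital_years: [1981, 2011]        # range, annual
#' migration_years: [1986, 1991, 1996, 2001, 2006, 2011]
#' break_year: 2004
#' baseline_year: 2011
#' tables:
#'   internal_migration: path.csv
#'   ...
#' baseline: baseline.csv
#' mcmc: {chains: 2, warmup: 500, samples: 500}
#' horizon_steps: 3
#' seed: 1
#' output_dir: out/
#' ```
#'
#' @param path YAML file path.
#' @return validated run-config list with materialised registries.
#' @export
read_run_config <- function(path) {
  rc <- yaml::read_yaml(path)
  need <- c("regions", "age_groups", "vital_years", "migration_years",
            "baseline_year", "tables", "baseline", "horizon_steps", "seed",
            "output_dir")
  missing <- setdiff(need, names(rc))
  if (length(missing))
    stop_mrpop("run config missing fields: %s", paste(missing, collapse = ", "))
  if (rc$horizon_steps < 1) stop_mrpop("horizon_steps must be >= 1")
  rc$vital_years <- seq(rc$vital_years[1], rc$vital_years[length(rc$vital_years)])
  rc$break_year <- rc$break_year %||% 2004L
  rc$mcmc <- do.call(mcmc_config, c(rc$mcmc %||% list(),
                                    list(seed = rc$seed)))
  for (cp in COMPONENTS) {
    p <- rc$tables[[cp]]
    if (is.null(p) || !file.exists(p))
      stop_mrpop("missing table file for component '%s'", cp)
  }
  if (!file.exists(rc$baseline)) stop_mrpop("missing baseline file")
  rc
}

pipeline_registry <- function(rc, component) {
  years <- if (component == "internal_migration") rc$migration_years
           else rc$vital_years
  dimension_registry(rc$regions, rc$age_groups, years)
}

read_baseline_csv <- function(path, registry, year) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  arr <- array(0, c(n_regions(registry), n_ages(registry), 2))
  idx <- cbind(match(df$region, registry$regions),
               match(df$age, registry$age_groups),
               match(df$sex, registry$sexes))
  if (anyNA(idx)) stop_mrpop("baseline file has unknown levels")
  arr[idx] <- df$population
  baseline_population(arr, registry, year)
}

draws_path <- function(rc, cp) file.path(rc$output_dir, paste0("draws_", cp, ".csv"))
forecast_path_csv <- function(rc, cp) file.path(rc$output_dir, paste0("forecast_", cp, ".csv"))

#' Fit all five component models and persist the draws
#'
#' One draws CSV (chain, iteration, named parameters) and one diagnostics
#' JSON per component are written to the output directory.
#'
#' @param rc a [read_run_config()] result.
#' @return named list of `mrpop_draws`, invisibly.
#' @export
cmd_fit <- function(rc) {
  dir.create(rc$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (cp in COMPONENTS) {
    reg <- pipeline_registry(rc, cp)
    tab <- tryCatch(read_component_table(rc$tables[[cp]], reg, cp),
                    error = function(e)
                      stop_mrpop("[%s] %s", cp, conditionMessage(e)))
    cfg <- rc$mcmc
    cfg$seed <- rc$seed + 10L * match(cp, COMPONENTS)
    spec <- default_model_spec(cp, break_year = rc$break_year)
    dr <- fit_component(spec, tab, cfg)
    per_chain <- cfg$samples
    meta <- data.frame(
      chain = rep(seq_len(cfg$chains), each = per_chain),
      iteration = rep(seq_len(per_chain), cfg$chains))
    utils::write.csv(cbind(meta, as.data.frame(dr$draws)),
                     draws_path(rc, cp), row.names = FALSE)
    jsonlite::write_json(
      list(component = cp, seed = cfg$seed,
           chains = cfg$chains, samples = cfg$samples, warmup = cfg$warmup,
           max_rhat = max(dr$diagnostics$rhat, na.rm = TRUE),
           min_ess = min(dr$diagnostics$ess, na.rm = TRUE),
           accept_lm = dr$accept_lm, warnings = dr$warnings),
      file.path(rc$output_dir, paste0("diagnostics_", cp, ".json")),
      auto_unbox = TRUE, digits = NA)
    out[[cp]] <- dr
  }
  invisible(out)
}

# Rebuild an mrpop_draws object from a persisted draws CSV.
load_draws <- function(rc, cp) {
  path <- draws_path(rc, cp)
  if (!file.exists(path))
    stop_mrpop("no draws file for component '%s'; run cmd_fit first", cp)
  df <- utils::read.csv(path, check.names = FALSE)
  mat <- as.matrix(df[, -(1:2), drop = FALSE])
  chains <- max(df$chain)
  structure(list(draws = mat, spec = default_model_spec(cp, rc$break_year),
                 registry = pipeline_registry(rc, cp), component = cp,
                 config = mcmc_config(chains = chains,
                                      samples = nrow(mat) / chains,
                                      warmup = 0, seed = rc$seed),
                 diagnostics = NULL, warnings = character(),
                 accept_lm = NA_real_, n_draws = nrow(mat)),
            class = "mrpop_draws")
}

#' Forecast all components over the projection horizon
#'
#' Annual components are forecast for every year of the horizon, internal
#' migration for every five-year period; per-component forecast CSVs are
#' written to the output directory.
#'
#' @param rc a [read_run_config()] result.
#' @return named list of `mrpop_forecast`s, invisibly.
#' @export
cmd_forecast <- function(rc) {
  out <- list()
  for (cp in COMPONENTS) {
    dr <- load_draws(rc, cp)
    last <- max(dr$registry$years)
    horizon <- if (cp == "internal_migration")
      last + 5L * seq_len(rc$horizon_steps)
    else last + seq_len(5L * rc$horizon_steps)
    fc <- forecast_component(dr, horizon,
                             seed = rc$seed + 100L + match(cp, COMPONENTS))
    write_forecast(fc, forecast_path_csv(rc, cp))
    out[[cp]] <- fc
  }
  invisible(out)
}

load_forecast <- function(rc, cp) {
  path <- forecast_path_csv(rc, cp)
  if (!file.exists(path))
    stop_mrpop("no forecast file for '%s'; run cmd_forecast first", cp)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = list(origin = "character",
                                          destination = "character",
                                          sex = "character"))
  base_reg <- pipeline_registry(rc, cp)
  years <- sort(unique(df$year))
  reg_f <- registry_with_years(base_reg, years)
  cells <- component_cell_grid(cp, reg_f)
  B <- max(df$draw)
  key_df <- paste(df$origin, df$destination, df$age, df$sex, df$year)
  df$destination[df$destination == ""] <- NA_character_
  df$sex[df$sex == ""] <- NA_character_
  key_df <- paste(df$origin, ifelse(is.na(df$destination), "", df$destination),
                  df$age, ifelse(is.na(df$sex), "", df$sex), df$year)
  key_cells <- paste(cells$origin,
                     ifelse(is.na(cells$destination), "", cells$destination),
                     cells$age, ifelse(is.na(cells$sex), "", cells$sex),
                     cells$year)
  mu <- matrix(NA_real_, B, nrow(cells))
  for (b in seq_len(B)) {
    sub <- df[df$draw == b, ]
    k <- paste(sub$origin, ifelse(is.na(sub$destination), "", sub$destination),
               sub$age, ifelse(is.na(sub$sex), "", sub$sex), sub$year)
    mu[b, ] <- sub$value[match(key_cells, k)]
  }
  structure(list(component = cp, cells = cells, mu = mu, years = years,
                 registry = reg_f, base_registry = base_reg,
                 kappa_paths = NULL, draw_index = seq_len(B)),
            class = "mrpop_forecast")
}

#' Project the population and write summaries and a run manifest
#'
#' Runs the multiregional cohort-component projection for every posterior
#' draw, then writes the draw-level population CSV, its quantile summary,
#' TFR and life-expectancy summaries for the final horizon year, and a
#' manifest JSON recording the seed and configuration hash.
#'
#' @param rc a [read_run_config()] result.
#' @param forecasts optional named list of in-memory `mrpop_forecast`s (to
#'   skip re-reading the stage files).
#' @return the `mrpop_popforecast`, invisibly.
#' @export
cmd_project <- function(rc, forecasts = NULL) {
  if (is.null(forecasts))
    forecasts <- stats::setNames(lapply(COMPONENTS, function(cp)
      load_forecast(rc, cp)), COMPONENTS)
  reg <- pipeline_registry(rc, "mortality")
  baseline <- read_baseline_csv(rc$baseline, reg, rc$baseline_year)
  pf <- project_horizon(baseline, forecasts, steps = rc$horizon_steps)
  write_popforecast(pf, file.path(rc$output_dir, "population_draws.csv"),
                    file.path(rc$output_dir, "population_summary.csv"))
  final_year <- max(forecasts$fertility$years)
  tfr_m <- tfr_draws(forecasts$fertility, final_year)
  utils::write.csv(cbind(region = colnames(tfr_m) %||% reg$regions,
                         summarize_draws(tfr_m)),
                   file.path(rc$output_dir, "tfr_summary.csv"),
                   row.names = FALSE)
  e0_list <- lapply(reg$sexes, function(s)
    cbind(sex = s, region = reg$regions,
          summarize_draws(e0_draws(forecasts$mortality, final_year, s))))
  utils::write.csv(do.call(rbind, e0_list),
                   file.path(rc$output_dir, "e0_summary.csv"),
                   row.names = FALSE)
  manifest <- list(
    seed = rc$seed,
    package_version = as.character(utils::packageVersion("mrpop")),
    horizon_steps = rc$horizon_steps,
    baseline_year = rc$baseline_year,
    n_draws = dim(pf$population)[1],
    excluded_draws = length(pf$excluded_draws),
    table_md5 = as.list(tools::md5sum(unlist(rc$tables))))
  jsonlite::write_json(manifest, file.path(rc$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(pf)
}
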