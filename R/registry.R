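#' Dimension registry for a multiregional population system
#'
#' Declares the regions, five-year age groups, sexes, observation years and
#' reproductive age window shared by all component tables and by the
#' projection engine.  Age groups are encoded by their integer lower bounds
#' (half-open intervals `[x, x+5)`), with the last group open-ended.
#'
#' @param regions character vector of region codes (at least 2).
#' @param age_groups strictly increasing integer lower bounds in steps of 5,
#'   e.g. `seq(0, 85, by = 5)` for the 18 groups 0-4 ... 85+.
#' @param years strictly increasing observation times with a constant step of
#'   1 (annual) or 5 (quinquennial).
#' @param reproductive_window integer pair of *age-group lower bounds*
#'   delimiting the first and last reproductive age groups (default 15 and 45,
#'   i.e. 15-19 through 45-49).
#' @param sexes ordered pair of sex codes, default `c("M", "F")`; a single
#'   code is accepted for single-sex tables (the projection engine requires
#'   both sexes).
#' @return an object of class `mrpop_registry`.
#' @examples
#' reg <- dimension_registry(c("A", "B"), seq(0, 85, 5), 1981:2011)
#' @export
dimension_registry <- function(regions, age_groups, years,
                               reproductive_window = c(15, 45),
                               sexes = c("M", "F")) {
  regions <- as.character(regions)
  age_groups <- as.integer(age_groups)
  years <- as.integer(years)
  if (length(regions) < 2 || anyDuplicated(regions))
    stop_mrpop("need at least 2 distinct regions")
  if (length(age_groups) < 2 || any(diff(age_groups) != 5L))
    stop_mrpop("age_groups must be >= 2 lower bounds increasing in steps of 5")
  if (length(years) < 1) stop_mrpop("years must be non-empty")
  if (length(years) > 1) {
    step <- unique(diff(years))
    if (length(step) != 1 || !step %in% c(1L, 5L))
      stop_mrpop("years must be strictly increasing with constant step 1 or 5")
  } else {
    step <- 1L
  }
  rw <- match(as.integer(reproductive_window), age_groups)
  if (anyNA(rw) || rw[1] > rw[2])
    stop_mrpop("reproductive_window must name age-group lower bounds with alpha <= beta")
  if (!length(sexes) %in% c(1L, 2L) || anyDuplicated(sexes))
    stop_mrpop("sexes must be one code or an ordered pair of distinct codes")
  structure(
    list(regions = regions, age_groups = age_groups, sexes = as.character(sexes),
         years = years, reproductive_window = rw, year_step = as.integer(step)),
    class = "mrpop_registry"
  )
}

#' @export
print.mrpop_registry <- function(x, ...) {
  cat("<mrpop_registry>\n")
  cat("  regions:", length(x$regions), paste0("(", paste(x$regions, collapse = ", "), ")"), "\n")
  cat("  age groups:", length(x$age_groups),
      sprintf("(%d-%d ... %d+)", x$age_groups[1], x$age_groups[1] + 4,
              x$age_groups[length(x$age_groups)]), "\n")
  cat("  years:", x$years[1], "-", x$years[length(x$years)],
      sprintf("(step %d)", x$year_step), "\n")
  cat("  reproductive window: groups", x$reproductive_window[1], "to",
      x$reproductive_window[2], "\n")
  invisible(x)
}

# Convenience accessors used internally.
n_regions <- function(reg) length(reg$regions)
n_ages <- function(reg) length(reg$age_groups)
n_years <- function(reg) length(reg$years)
reproductive_ages <- function(reg) {
  reg$age_groups[reg$reproductive_window[1]:reg$reproductive_window[2]]
}

# Derive a registry identical to `reg` but with a different year grid
# (annual vital series and quinquennial migration series share regions/ages).
registry_with_years <- function(reg, years) {
  dimension_registry(reg$regions, reg$age_groups, years,
                     reg$age_groups[reg$reproductive_window], reg$sexes)
}

#' Baseline population array
#'
#' Wraps a region x age x sex array of persons at the projection jump-off
#' year.  The baseline is treated as known (error-free) by the projection
#' engine.
#'
#' @param values numeric array `n x z x 2`, dimnames matching the registry,
#'   all entries non-negative.
#' @param registry a [dimension_registry()].
#' @param year baseline (jump-off) year.
#' @return an object of class `mrpop_baseline`.
#' @export
baseline_population <- function(values, registry, year) {
  values <- as.array(values)
  dims <- dim(values)
  if (length(dims) != 3 ||
      dims[1] != n_regions(registry) ||
      dims[2] != n_ages(registry) || dims[3] != 2)
    stop_mrpop("baseline values must be a region x age x sex array matching the registry")
  if (any(!is.finite(values)) || any(values < 0))
    stop_mrpop("baseline population entries must be finite and >= 0")
  dimnames(values) <- list(registry$regions, registry$age_groups, registry$sexes)
  structure(list(values = values, registry = registry, year = as.integer(year)),
            class = "mrpop_baseline")
}

#' @export
print.mrpop_baseline <- function(x, ...) {
  cat("<mrpop_baseline> year", x$year, "- total population",
      format(round(sum(x$values))), "\n")
  invisible(x)
}
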