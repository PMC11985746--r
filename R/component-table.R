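#' @keywords internal
COMPONENTS <- c("internal_migration", "mortality", "fertility",
                "immigration", "emigration")

component_has_sex <- function(component) component != "fertility"
component_has_destination <- function(component) component == "internal_migration"

# Canonical cell grid for a component: every declared combination exactly
# once, diagonal excluded for migration, fertility restricted to the
# reproductive window and (implicitly) to women.
component_cell_grid <- function(component, registry) {
  ages <- if (component == "fertility") reproductive_ages(registry) else registry$age_groups
  if (component == "internal_migration") {
    g <- expand.grid(origin = registry$regions, destination = registry$regions,
                     age = ages, sex = registry$sexes, year = registry$years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g <- g[g$origin != g$destination, , drop = FALSE]
  } else if (component == "fertility") {
    g <- expand.grid(origin = registry$regions, age = ages, year = registry$years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$destination <- NA_character_
    g$sex <- NA_character_
  } else {
    g <- expand.grid(origin = registry$regions, age = ages,
                     sex = registry$sexes, year = registry$years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$destination <- NA_character_
  }
  g <- g[, c("origin", "destination", "age", "sex", "year")]
  g$age <- as.integer(g$age)
  g$year <- as.integer(g$year)
  rownames(g) <- NULL
  g
}

cell_key <- function(cells) {
  paste(cells$origin,
        ifelse(is.na(cells$destination), "", cells$destination),
        cells$age,
        ifelse(is.na(cells$sex), "", cells$sex),
        cells$year, sep = "|")
}

#' Construct a validated component table
#'
#' A component table is the universal long-format input for all five
#' demographic components: one row per cross-classified cell with a
#' non-negative event count `count` and a positive exposure `exposure`
#' (person-years or persons at risk; identically 1 for immigration, which is
#' modelled as counts).
#'
#' @param component one of `"internal_migration"`, `"mortality"`,
#'   `"fertility"`, `"immigration"`, `"emigration"`.
#' @param cells data frame with columns `origin`, `destination` (migration
#'   only, otherwise `NA`), `age`, `sex` (`NA` for fertility), `year`,
#'   `count`, `exposure`.
#' @param registry a [dimension_registry()] whose `years` match the table.
#' @return an object of class `mrpop_table`.
#' @export
component_table <- function(component, cells, registry) {
  component <- match.arg(component, COMPONENTS)
  req <- c("origin", "destination", "age", "sex", "year", "count", "exposure")
  missing_cols <- setdiff(req, names(cells))
  if (length(missing_cols))
    stop_mrpop("schema mismatch: missing columns %s",
               paste(missing_cols, collapse = ", "))
  cells <- as.data.frame(cells)[, req]
  cells$origin <- as.character(cells$origin)
  cells$destination <- as.character(cells$destination)
  cells$sex <- as.character(cells$sex)
  cells$age <- as.integer(cells$age)
  cells$year <- as.integer(cells$year)
  cells$exposure <- as.numeric(cells$exposure)
  cells$count <- as.numeric(cells$count)

  if (component == "fertility" && any(!is.na(cells$sex) & cells$sex != "F"))
    stop_mrpop("fertility restricted to females")
  if (component == "fertility") cells$sex <- NA_character_
  if (!component_has_destination(component) && any(!is.na(cells$destination)))
    stop_mrpop("destination only applies to internal migration")

  extra_regions <- setdiff(stats::na.omit(c(cells$origin, cells$destination)),
                           registry$regions)
  if (length(extra_regions))
    stop_mrpop("unknown region level(s): %s", paste(extra_regions, collapse = ", "))
  allowed_ages <- if (component == "fertility") reproductive_ages(registry)
                  else registry$age_groups
  if (length(setdiff(cells$age, allowed_ages))) {
    if (component == "fertility" &&
        all(setdiff(cells$age, allowed_ages) %in% registry$age_groups))
      stop_mrpop("fertility cells must lie in the reproductive window")
    stop_mrpop("unknown age level(s): %s",
               paste(setdiff(cells$age, allowed_ages), collapse = ", "))
  }
  if (length(setdiff(stats::na.omit(cells$sex), registry$sexes)))
    stop_mrpop("unknown sex level(s)")
  if (length(setdiff(cells$year, registry$years)))
    stop_mrpop("unknown year level(s): %s",
               paste(setdiff(cells$year, registry$years), collapse = ", "))
  if (component == "internal_migration" &&
      any(cells$origin == cells$destination))
    stop_mrpop("migration tables must exclude the diagonal (origin == destination)")

  if (any(!is.finite(cells$count)) || any(cells$count < 0) ||
      any(cells$count != round(cells$count)))
    stop_mrpop("counts must be non-negative integers")
  if (any(!is.finite(cells$exposure)) || any(cells$exposure <= 0))
    stop_mrpop("exposures must be positive")
  if (component == "immigration" && any(cells$exposure != 1))
    stop_mrpop("immigration is modelled as counts: exposure must be identically 1")

  grid <- component_cell_grid(component, registry)
  key <- cell_key(cells)
  if (anyDuplicated(key)) stop_mrpop("duplicate cells in table")
  gkey <- cell_key(grid)
  pos <- match(gkey, key)
  if (anyNA(pos))
    stop_mrpop("incomplete cross-classification: %d of %d cells missing",
               sum(is.na(pos)), nrow(grid))
  if (nrow(cells) != nrow(grid))
    stop_mrpop("table has %d cells but the registry declares %d",
               nrow(cells), nrow(grid))
  cells <- cells[pos, , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(component = component, cells = cells, registry = registry),
            class = "mrpop_table")
}

#' @export
print.mrpop_table <- function(x, ...) {
  cat("<mrpop_table>", x$component, "-", nrow(x$cells), "cells,",
      "years", min(x$cells$year), "-", max(x$cells$year), "\n")
  invisible(x)
}

#' Read a component table from a long-format CSV file
#'
#' The file must have a header
#' `component,origin,destination,age,sex,year,count,exposure` with
#' `destination` empty for non-migration components and `sex` empty for
#' fertility.  The table is validated against the registry: missing
#' combinations, duplicates, unknown levels, negative counts and non-positive
#' exposures all raise errors.
#'
#' @inheritParams component_table
#' @param path path to a CSV file.
#' @return an [component_table()] object.
#' @export
read_component_table <- function(path, registry, component) {
  component <- match.arg(component, COMPONENTS)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = list(origin = "character",
                                          destination = "character",
                                          sex = "character"))
  req <- c("component", "origin", "destination", "age", "sex", "year",
           "count", "exposure")
  if (!all(req %in% names(df)))
    stop_mrpop("schema mismatch: expected columns %s", paste(req, collapse = ","))
  if (any(df$component != component))
    stop_mrpop("file contains component '%s' but '%s' was requested",
               df$component[df$component != component][1], component)
  df$destination[df$destination == ""] <- NA_character_
  df$sex[df$sex == ""] <- NA_character_
  component_table(component, df, registry)
}

#' Write a component table to CSV
#'
#' Inverse of [read_component_table()]; the round trip preserves the cell
#' set, counts and exposures exactly.
#'
#' @param table an `mrpop_table`.
#' @param path output path.
#' @export
write_component_table <- function(table, path) {
  stopifnot(inherits(table, "mrpop_table"))
  out <- cbind(component = table$component, table$cells)
  out$destination[is.na(out$destination)] <- ""
  out$sex[is.na(out$sex)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cohort-aligned exposures for quinquennial migration transitions
#'
#' Transition-format migration data record moves over a five-year interval
#' `(t-5, t]` at the *terminal* age `x`; the population at risk is the origin
#' population five years earlier at age `x - 5`.  Migrants recorded in the
#' first age group (children born during the interval) take the start-of-
#' period population of that same first age group as exposure.
#'
#' @param populations region x age x sex x year numeric array of mid-year (or
#'   start-of-period) populations; its `year` dimension must include `t - 5`
#'   for every migration observation year `t`.  Dimnames are required on the
#'   `year` margin.
#' @param registry a quinquennial [dimension_registry()] describing the
#'   migration observation years.
#' @return a data frame `origin, age, sex, year, exposure` covering the full
#'   migration grid (exposure does not depend on destination).
#' @export
lag_exposure_for_migration <- function(populations, registry) {
  yrs <- dimnames(populations)[[4]]
  if (is.null(yrs)) stop_mrpop("populations array needs year dimnames")
  grid <- expand.grid(origin = registry$regions, age = registry$age_groups,
                      sex = registry$sexes, year = registry$years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lag_year <- as.character(grid$year - 5L)
  if (length(setdiff(unique(lag_year), yrs)))
    stop_mrpop("missing lagged year(s): %s",
               paste(setdiff(unique(lag_year), yrs), collapse = ", "))
  ai <- match(grid$age, registry$age_groups)
  # cohort shift: terminal age x exposed at x-5; first group maps to itself
  ai_lag <- pmax(ai - 1L, 1L)
  idx <- cbind(match(grid$origin, registry$regions), ai_lag,
               match(grid$sex, registry$sexes), match(lag_year, yrs))
  grid$exposure <- populations[idx]
  if (any(!is.finite(grid$exposure) | grid$exposure <= 0))
    stop_mrpop("non-positive exposure for some cohort-aligned cells")
  grid$age <- as.integer(grid$age)
  grid$year <- as.integer(grid$year)
  rownames(grid) <- NULL
  grid
}
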