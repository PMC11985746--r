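# Data model: dimension registry, component tables, I/O, exposure lagging.

test_that("dimension registry enforces its invariants", {
  expect_s3_class(small_registry(), "mrpop_registry")
  expect_error(dimension_registry("A", seq(0, 85, 5), 2001:2010),
               "2 distinct regions")
  expect_error(dimension_registry(c("A", "B"), c(0, 4), 2001:2010),
               "steps of 5")
  expect_error(dimension_registry(c("A", "B"), seq(0, 85, 5),
                                  c(2001, 2003, 2005)), "step 1 or 5")
  expect_error(dimension_registry(c("A", "B"), seq(0, 85, 5), 2001:2010,
                                  reproductive_window = c(45, 15)),
               "alpha <= beta")
  # quinquennial grids are accepted
  reg <- dimension_registry(c("A", "B"), seq(0, 85, 5), seq(1986, 2011, 5))
  expect_identical(reg$year_step, 5L)
})

test_that("a minimal complete migration table validates and a missing cell fails", {
  reg <- tiny_migration_registry()
  cells <- tiny_migration_cells()
  tab <- component_table("internal_migration", cells, reg)
  expect_identical(nrow(tab$cells), 4L)
  expect_error(component_table("internal_migration", cells[-2, ], reg),
               "incomplete cross-classification")
  dup <- rbind(cells, cells[1, ])
  expect_error(component_table("internal_migration", dup, reg), "duplicate")
})

test_that("component tables reject invalid counts, exposures and levels", {
  reg <- tiny_migration_registry()
  cells <- tiny_migration_cells()
  bad <- cells; bad$count[1] <- -1
  expect_error(component_table("internal_migration", bad, reg),
               "non-negative integers")
  bad <- cells; bad$exposure[2] <- 0
  expect_error(component_table("internal_migration", bad, reg), "positive")
  bad <- cells; bad$origin[1] <- "Z"
  expect_error(component_table("internal_migration", bad, reg),
               "unknown region")
  bad <- cells; bad$destination[1] <- "A"  # diagonal cell
  expect_error(component_table("internal_migration", bad, reg), NULL)
})

test_that("fertility tables are restricted to females in the window", {
  reg <- dimension_registry(c("A", "B"), seq(0, 85, 5), 2005,
                            reproductive_window = c(15, 45))
  ages <- seq(15, 45, 5)
  cells <- expand.grid(origin = c("A", "B"), age = ages, year = 2005,
                       stringsAsFactors = FALSE)
  cells$destination <- NA; cells$sex <- NA
  cells$count <- 10L; cells$exposure <- 1000
  tab <- component_table("fertility", cells, reg)
  expect_identical(nrow(tab$cells), 2L * 7L)
  male <- cells; male$sex[1] <- "M"
  expect_error(component_table("fertility", male, reg),
               "restricted to females")
  outside <- cells; outside$age[1] <- 50
  expect_error(component_table("fertility", outside, reg),
               "reproductive window|incomplete")
})

test_that("immigration exposure must be identically one", {
  reg <- dimension_registry(c("A", "B"), c(0, 5), 2005,
                            reproductive_window = c(0, 0), sexes = "M")
  cells <- expand.grid(origin = c("A", "B"), age = c(0, 5), sex = "M",
                       year = 2005, stringsAsFactors = FALSE)
  cells$destination <- NA; cells$count <- 100L; cells$exposure <- 1
  expect_s3_class(component_table("immigration", cells, reg), "mrpop_table")
  cells$exposure <- 2
  expect_error(component_table("immigration", cells, reg), "identically 1")
})

test_that("read/write round-trips a component table bit-exactly", {
  reg <- tiny_migration_registry()
  tab <- component_table("internal_migration", tiny_migration_cells(), reg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_component_table(tab, path)
  back <- read_component_table(path, reg, "internal_migration")
  expect_identical(back$cells, tab$cells)
  expect_error(read_component_table(path, reg, "mortality"), "component")
})

test_that("cell count equals the product of declared dimension sizes", {
  cfg <- small_generator_config()
  for (cp in c("mortality", "fertility", "immigration")) {
    tr <- draw_true_parameters(cfg, cp)
    tab <- simulate_component_table(tr, cfg, cp)
    n <- 3; z <- 18; T <- 15
    expected <- switch(cp,
      mortality = n * z * 2 * T,
      fertility = n * 7 * T,
      immigration = n * z * 2 * T)
    expect_identical(nrow(tab$cells), as.integer(expected))
  }
})

test_that("migration exposures are cohort-aligned to the origin population", {
  reg <- dimension_registry(c("A", "B"), seq(0, 85, 5), 2011,
                            reproductive_window = c(15, 45))
  z <- 18
  pops <- array(0, c(2, z, 2, 1), dimnames = list(c("A", "B"), seq(0, 85, 5),
                                                  c("M", "F"), 2006))
  pops["A", , , 1] <- 500
  pops["B", , , 1] <- 700
  pops["A", "20", "M", 1] <- 1000   # age 20-24 in 2006
  ex <- lag_exposure_for_migration(pops, reg)
  # terminal age 25-29 in 2011 is exposed at age 20-24 in 2006
  got <- ex$exposure[ex$origin == "A" & ex$age == 25 & ex$sex == "M"]
  expect_equal(got, 1000)
  # first age group maps to itself (children born during the interval)
  got0 <- ex$exposure[ex$origin == "A" & ex$age == 0 & ex$sex == "M"]
  expect_equal(got0, 500)
  # uniform population gives that constant everywhere
  pops[] <- 250
  exu <- lag_exposure_for_migration(pops, reg)
  expect_true(all(exu$exposure == 250))
  # missing lagged year raises
  dimnames(pops)[[4]] <- "2007"
  expect_error(lag_exposure_for_migration(pops, reg), "missing lagged year")
  # zero population at risk raises
  dimnames(pops)[[4]] <- "2006"
  pops["A", "20", "M", 1] <- 0
  expect_error(lag_exposure_for_migration(pops, reg), "non-positive exposure")
})
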