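# Shared fixture builders for the test suite.  Everything is generated in
# code; sizes are kept small so individual fits run in seconds.

small_registry <- function(years = 2001:2010, regions = c("A", "B", "C")) {
  dimension_registry(regions, seq(0, 85, by = 5), years)
}

# A minimal complete 2-region, 2-age, 1-year migration table.
tiny_migration_cells <- function() {
  data.frame(
    origin = c("A", "B", "A", "B"),
    destination = c("B", "A", "B", "A"),
    age = c(0L, 0L, 5L, 5L),
    sex = "M",
    year = 2006L,
    count = c(3L, 5L, 2L, 4L),
    exposure = c(100, 120, 90, 110))
}

tiny_migration_registry <- function() {
  dimension_registry(c("A", "B"), c(0, 5), 2006, reproductive_window = c(0, 0),
                     sexes = "M")
}

# Small generator configuration used across fitting tests: 3 regions, full
# age range, 15 annual years / 4 quinquennial migration periods.
small_generator_config <- function(seed = 42) {
  generator_config(seed = seed, regions = c("A", "B", "C"),
                   age_groups = seq(0, 85, by = 5),
                   vital_years = 1997:2011,
                   migration_years = seq(1996, 2011, by = 5),
                   region_pop = c(2e6, 1e6, 5e5))
}

# Independent single-region cohort-component projection written with scalar
# arithmetic only (no matrices, no package projection functions); the
# uniregional oracle for the zero-migration equivalence property.
uniregional_oracle_step <- function(K, d, e, f, G, srb = 105,
                                    alpha_idx, beta_idx) {
  z <- ncol(K)  # K is 2 x z (sexes M, F)
  pde <- function(dd, ee) (1 - 2.5 * (dd + ee)) / (1 + 2.5 * (dd + ee))
  newK <- matrix(0, 2, z)
  for (s in 1:2) {
    P <- vapply(seq_len(z), function(a) pde(d[s, a], e[s, a]), 0)
    S <- numeric(z)
    for (a in seq_len(z)) {
      Pnext <- if (a < z) P[a + 1] else P[z]
      S[a] <- (1 + Pnext) * P[a] / (1 + P[a])
    }
    for (a in seq_len(z - 1))
      newK[s, a + 1] <- S[a] * (K[s, a] + G[s, a] / 2) + G[s, a + 1] / 2
    newK[s, z] <- newK[s, z] + S[z] * (K[s, z] + G[s, z] / 2)
  }
  # births (female exposure), survived with the infant survivorship scalar
  sum_term <- 0
  Pf <- vapply(seq_len(z), function(a) pde(d[2, a], e[2, a]), 0)
  Sf <- numeric(z)
  for (a in seq_len(z)) {
    Pnext <- if (a < z) Pf[a + 1] else Pf[z]
    Sf[a] <- (1 + Pnext) * Pf[a] / (1 + Pf[a])
  }
  for (a in alpha_idx:beta_idx) {
    fnext <- if (a + 1 <= z) f[a + 1] else 0
    sum_term <- sum_term + (f[a] + Sf[a] * fnext) * (K[2, a] + G[2, a] / 2)
  }
  births <- 2.5 * sum_term
  s_minus5 <- function(P0) 1 / (1 + (1 - P0) / (1 + P0))
  Pm <- pde(d[1, 1], e[1, 1])
  Pf0 <- pde(d[2, 1], e[2, 1])
  newK[1, 1] <- s_minus5(Pm) * births * srb / (100 + srb) + G[1, 1] / 2
  newK[2, 1] <- s_minus5(Pf0) * births * 100 / (100 + srb) + G[2, 1] / 2
  newK
}

# Independent textbook abridged life table (separate implementation from
# life_expectancy_at_birth): q from m with a = 2.5, l-column, person-years,
# 1/m closure of the open-ended group.
life_table_oracle <- function(m) {
  z <- length(m)
  lx <- 1
  total <- 0
  for (a in seq_len(z - 1)) {
    qx <- 5 * m[a] / (1 + 2.5 * m[a])
    lnext <- lx * (1 - qx)
    total <- total + 5 * (lx + lnext) / 2
    lx <- lnext
  }
  total + (if (lx > 0) lx / m[z] else 0)
}
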