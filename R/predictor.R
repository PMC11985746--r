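# Log-bilinear predictor machinery: term-level indexing of cross-classified
# cells, evaluation of the additive log-scale predictor, the sum-to-one
# constraint and prior for bilinear loadings, the symmetric origin-
# destination prior, and the Poisson-lognormal likelihood contribution.

# Ordered origin-destination pairs (i != j), origin varying fastest; this is
# the canonical "od" dimension order used everywhere.
od_pairs <- function(regions) {
  g <- expand.grid(origin = regions, destination = regions,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[g$origin != g$destination, , drop = FALSE]
  rownames(g) <- NULL
  g
}

od_labels <- function(regions) {
  p <- od_pairs(regions)
  paste(p$origin, p$destination, sep = ">")
}

# Unordered pairs {i, j}, i before j in registry order; the free parameters
# of the symmetric origin-destination prior.
unordered_pairs <- function(regions) {
  n <- length(regions)
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  data.frame(a = regions[i], b = regions[j], stringsAsFactors = FALSE)
}

# Map each ordered od pair to its unordered pair index.
od_to_unordered <- function(regions) {
  p <- od_pairs(regions)
  up <- unordered_pairs(regions)
  key <- ifelse(match(p$origin, regions) < match(p$destination, regions),
                paste(p$origin, p$destination), paste(p$destination, p$origin))
  match(key, paste(up$a, up$b))
}

# Dimension level sets for a component's cells.
dim_levels <- function(dim, component, registry) {
  switch(dim,
    origin = , region = , destination = registry$regions,
    od = od_labels(registry$regions),
    age = if (component == "fertility") reproductive_ages(registry)
          else registry$age_groups,
    sex = registry$sexes,
    stop_mrpop("unknown term dimension '%s'", dim))
}

# Per-cell value of a dimension (character), for index construction.
dim_values <- function(dim, cells) {
  switch(dim,
    origin = , region = cells$origin,
    destination = cells$destination,
    od = paste(cells$origin, cells$destination, sep = ">"),
    age = as.character(cells$age),
    sex = cells$sex,
    stop_mrpop("unknown term dimension '%s'", dim))
}

# Build integer index (cell -> parameter level) and level labels for a term.
term_index <- function(term, cells, component, registry) {
  if (term$kind == "intercept")
    return(list(idx = rep.int(1L, nrow(cells)), labels = "c"))
  dims <- term$dims
  levs <- lapply(dims, dim_levels, component = component, registry = registry)
  vals <- lapply(dims, dim_values, cells = cells)
  idx <- match(vals[[1]], as.character(levs[[1]]))
  labels <- as.character(levs[[1]])
  if (length(dims) > 1) {
    for (k in 2:length(dims)) {
      ik <- match(vals[[k]], as.character(levs[[k]]))
      idx <- idx + (ik - 1L) * prod(lengths(levs)[1:(k - 1)])
      labels <- as.vector(outer(labels, as.character(levs[[k]]), paste, sep = ","))
    }
  }
  if (anyNA(idx)) stop_mrpop("unknown cell level for term '%s'", term$name)
  list(idx = as.integer(idx), labels = labels)
}

# Assemble the full evaluation frame for a model spec on a set of cells.
# Each term gets: idx, labels, L, active flags (break terms), and for
# bilinear loadings the group structure and kappa time/sex indices.
build_frame <- function(spec, cells, registry) {
  component <- spec$component
  tidx <- match(cells$year, registry$years)
  if (anyNA(tidx)) stop_mrpop("cell year outside the registry year grid")
  sidx <- match(cells$sex, registry$sexes)
  kmap <- stats::setNames(lapply(spec$kappas, function(ks) {
    list(name = ks$name, dynamics = ks$dynamics, sex_paired = ks$sex_paired,
         T = n_years(registry), years = registry$years)
  }), vapply(spec$kappas, `[[`, "", "name"))
  terms <- lapply(spec$terms, function(tm) {
    ti <- term_index(tm, cells, component, registry)
    out <- list(name = tm$name, kind = tm$kind, prior = tm$prior,
                idx = ti$idx, labels = ti$labels, L = length(ti$labels))
    if (tm$kind == "break_indicator")
      out$active <- cells$year >= tm$break_year
    if (tm$kind == "bilinear_loading") {
      ks <- kmap[[tm$kappa]]
      if (is.null(ks)) stop_mrpop("term '%s' names unknown kappa '%s'",
                                  tm$name, tm$kappa)
      out$kappa <- tm$kappa
      out$tidx <- tidx
      out$ksex <- if (ks$sex_paired) sidx else rep.int(1L, nrow(cells))
      if (identical(tm$group_dim, "sex")) {
        out$gidx <- sidx
        out$n_groups <- 2L
        out$group_labels <- registry$sexes
      } else {
        out$gidx <- rep.int(1L, nrow(cells))
        out$n_groups <- 1L
        out$group_labels <- ""
      }
    }
    out
  })
  names(terms) <- vapply(spec$terms, `[[`, "", "name")
  list(component = component, cells = cells, registry = registry,
       terms = terms, kappas = kmap, tidx = tidx, sidx = sidx,
       n = nrow(cells))
}

# Contribution of a single term to the predictor, given sampler state.
term_contribution <- function(tm, state, frame) {
  if (tm$kind == "bilinear_loading") {
    load <- state$loading[[tm$name]]    # matrix n_groups x L (full, sums to 1)
    kap <- state$kappa[[tm$kappa]]      # matrix n_sex(1|2) x T
    a <- load[cbind(tm$gidx, tm$idx)]
    k <- kap[cbind(tm$ksex, tm$tidx)]
    a * k
  } else {
    v <- state$coef[[tm$name]][tm$idx]
    if (!is.null(tm$active)) v <- v * tm$active
    v
  }
}

eval_predictor <- function(frame, state) {
  M <- numeric(frame$n)
  for (tm in frame$terms) M <- M + term_contribution(tm, state, frame)
  M
}

#' Evaluate the additive log-scale predictor of a log-bilinear model
#'
#' Sums, for each supplied cell, the contributions of every term in the
#' model specification: intercept, main effects and interactions indexed by
#' the cell's dimension levels, bilinear terms as `loading * kappa` at the
#' cell's time (and sex, for sex-paired series), and break indicators only
#' for years at or past their threshold.
#'
#' @param spec an [default_model_spec()]-style specification.
#' @param params named list mapping each non-bilinear term name to a vector
#'   of level values (in the term's canonical level order) and each bilinear
#'   loading name to its full loading vector (matrix sex x level when the
#'   loading is sex-grouped).
#' @param kappa_values named list mapping each kappa series to a vector of
#'   length `T` (matrix `2 x T` for sex-paired series) on the registry year
#'   grid.
#' @param cells data frame of cells (`origin`, `destination`, `age`, `sex`,
#'   `year` as applicable).
#' @param registry the [dimension_registry()].
#' @return numeric vector of log-scale predictors, one per cell.
#' @export
linear_predictor <- function(spec, params, kappa_values, cells, registry) {
  frame <- build_frame(spec, as.data.frame(cells), registry)
  state <- list(coef = list(), loading = list(), kappa = list())
  for (tm in frame$terms) {
    p <- params[[tm$name]]
    if (is.null(p)) stop_mrpop("params missing term '%s'", tm$name)
    if (tm$kind == "bilinear_loading") {
      m <- if (is.matrix(p)) p else matrix(p, nrow = 1)
      if (ncol(m) != tm$L || nrow(m) != tm$n_groups)
        stop_mrpop("loading '%s' must be %d x %d", tm$name, tm$n_groups, tm$L)
      state$loading[[tm$name]] <- m
    } else {
      if (length(p) != tm$L)
        stop_mrpop("term '%s' needs %d values, got %d", tm$name, tm$L, length(p))
      state$coef[[tm$name]] <- as.numeric(p)
    }
  }
  for (kn in names(frame$kappas)) {
    kv <- kappa_values[[kn]]
    if (is.null(kv)) stop_mrpop("kappa_values missing series '%s'", kn)
    km <- if (is.matrix(kv)) kv else matrix(kv, nrow = 1)
    if (ncol(km) != n_years(registry))
      stop_mrpop("kappa '%s' must have one value per registry year", kn)
    state$kappa[[kn]] <- km
  }
  eval_predictor(frame, state)
}

#' Complete a constrained bilinear loading vector
#'
#' Appends the implied last element `1 - sum(u)` so the returned loading
#' sums to exactly one (the identifiability constraint on bilinear terms).
#'
#' @param u free loading values (length `L - 1`).
#' @return numeric vector of length `L` summing to 1.
#' @export
constrain_bilinear_loadings <- function(u) {
  u <- as.numeric(u)
  c(u, 1 - sum(u))
}

# Precision matrix Psi (diagonal 2, off-diagonal 1) scaled by L^2: the prior
# precision of the free loading values.
bilinear_prior_precision <- function(L) {
  m <- L - 1L
  Psi <- matrix(1, m, m)
  diag(Psi) <- 2
  L^2 * Psi
}

#' Log prior density of free bilinear loading values
#'
#' The free values `u` (all but the last loading element) are multivariate
#' normal with mean `1/L` and covariance `L^-2 Psi^-1`, where `Psi` is the
#' `(L-1) x (L-1)` matrix with 2 on the diagonal and 1 elsewhere and `L` is
#' the full loading length.
#'
#' @param u free loading values (length `L - 1`, `L >= 2`).
#' @return scalar log density.
#' @export
bilinear_prior_logdensity <- function(u) {
  u <- as.numeric(u)
  m <- length(u)
  if (m < 1) stop_mrpop("need at least one free loading value")
  L <- m + 1L
  Q <- bilinear_prior_precision(L)
  d <- u - 1 / L
  # log det Q = log det(L^2 Psi); det(Psi) = m + 1 for the 2/1 pattern
  logdetQ <- 2 * m * log(L) + log(m + 1)
  -0.5 * (m * log(2 * pi) - logdetQ + drop(crossprod(d, Q %*% d)))
}

#' Symmetric origin-destination prior log density
#'
#' The origin-destination level term `OD1` is normal around a symmetric
#' matrix of means: `OD1[i,j] ~ N(alpha[i,j], sigma_od^2)` with
#' `alpha[i,j] = alpha[j,i]`, so opposite flows share a common prior centre.
#'
#' @param alpha free symmetric means, length `n(n-1)/2`, ordered by
#'   unordered region pair (first region before second in registry order).
#' @param od1 origin-destination values, length `n(n-1)`, in canonical
#'   ordered-pair order (origin varying fastest).
#' @param sigma_od positive spread around the symmetric means.
#' @param regions region codes defining the pair orders.
#' @return scalar log density (sum over all ordered pairs).
#' @export
symmetric_od_prior <- function(alpha, od1, sigma_od, regions) {
  n <- length(regions)
  if (length(alpha) != n * (n - 1) / 2)
    stop_mrpop("alpha must have n(n-1)/2 = %d values", n * (n - 1) / 2)
  if (length(od1) != n * (n - 1))
    stop_mrpop("od1 must have n(n-1) = %d values", n * (n - 1))
  if (sigma_od <= 0) stop_mrpop("sigma_od must be positive")
  mu <- alpha[od_to_unordered(regions)]
  sum(stats::dnorm(od1, mu, sigma_od, log = TRUE))
}

#' Poisson-lognormal likelihood contribution of one cell
#'
#' Joint log density of the augmented-likelihood form: the count is Poisson
#' with mean `exp(log_mu) * K`, and the latent log rate `log_mu` is normal
#' around the model predictor `M` with overdispersion sd `sigma`.  The
#' latent is a per-cell parameter; it is not marginalised out.
#'
#' @param Y non-negative integer count.
#' @param K positive exposure.
#' @param log_mu latent log rate.
#' @param M log-scale predictor.
#' @param sigma overdispersion standard deviation (> 0).
#' @return scalar log density.
#' @export
poisson_lognormal_loglik <- function(Y, K, log_mu, M, sigma) {
  if (any(K <= 0)) stop_mrpop("exposure must be positive")
  if (any(sigma <= 0)) stop_mrpop("sigma must be positive")
  if (any(Y < 0) || any(Y != round(Y)))
    stop_mrpop("counts must be non-negative integers")
  stats::dpois(Y, exp(log_mu) * K, log = TRUE) +
    stats::dnorm(log_mu, M, sigma, log = TRUE)
}
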