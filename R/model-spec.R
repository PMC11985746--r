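# Declarative description of a log-bilinear predictor: which additive terms
# enter the log-mean, which bilinear loading/kappa pairs, which latent
# time-series dynamics, and the priors on everything.

#' Prior specifications
#'
#' * `prior_normal(mean, sd)` — normal with fixed standard deviation (used
#'   for the intercept, variance 5 i.e. sd `sqrt(5)`, and for two-way
#'   interactions, sd 0.2).
#' * `prior_hier_normal(df, scale)` — zero-mean normal whose standard
#'   deviation gets a half-t hyperprior (main-effect profiles).
#' * `prior_symmetric_od(alpha_sd, df, scale)` — origin-destination term
#'   centred on a symmetric matrix `alpha` (`alpha[i,j] == alpha[j,i]`) with
#'   standard-normal prior on the free `alpha` values and a half-t prior on
#'   the spread around them.
#' * `prior_constrained_bilinear()` — loading vector of length `L` whose
#'   first `L - 1` elements are multivariate normal with mean `1/L` and
#'   covariance `L^-2 Psi^-1` (`Psi` has 2 on the diagonal, 1 off it), the
#'   last element being `1 - sum` so the loading sums to exactly 1.
#'
#' @param mean,sd normal moments.
#' @param df,scale half-t hyperparameters.
#' @param alpha_sd prior sd of the symmetric origin-destination means.
#' @return a list describing the prior, used inside [model_term()].
#' @name priors
NULL

#' @rdname priors
#' @export
prior_normal <- function(mean = 0, sd = 1) {
  stopifnot(sd > 0)
  list(family = "normal_fixed_sd", mean = mean, sd = sd)
}

#' @rdname priors
#' @export
prior_hier_normal <- function(df = 2.5, scale = 0.5) {
  stopifnot(df > 0, scale > 0)
  list(family = "normal_hier_sd_half_t", df = df, scale = scale)
}

#' @rdname priors
#' @export
prior_symmetric_od <- function(alpha_sd = 1, df = 2.5, scale = 0.5) {
  stopifnot(alpha_sd > 0, df > 0, scale > 0)
  list(family = "symmetric_od_normal", alpha_sd = alpha_sd, df = df, scale = scale)
}

#' @rdname priors
#' @export
prior_constrained_bilinear <- function() {
  list(family = "constrained_bilinear")
}

#' Define one additive term of a log-bilinear predictor
#'
#' @param name term label (used to name parameters in posterior draws).
#' @param dims character vector of cell dimensions the term is indexed by:
#'   any of `"origin"`, `"destination"`, `"od"` (ordered origin-destination
#'   pair), `"age"`, `"sex"`, `"region"` (alias for `origin` in non-migration
#'   components); empty for the intercept.
#' @param kind `"intercept"`, `"main"`, `"interaction"`,
#'   `"bilinear_loading"` or `"break_indicator"`.
#' @param prior a prior from [priors].
#' @param kappa for bilinear loadings, the name of the paired kappa series.
#' @param group_dim for bilinear loadings whose kappa series is sex-paired
#'   and whose loading is estimated separately per sex, `"sex"`.
#' @param break_year for break indicators, the threshold year (the term
#'   contributes only for `year >= break_year`).
#' @return a term-spec list.
#' @export
model_term <- function(name, dims = character(), kind = "main",
                       prior = prior_hier_normal(), kappa = NULL,
                       group_dim = NULL, break_year = NULL) {
  kind <- match.arg(kind, c("intercept", "main", "interaction",
                            "bilinear_loading", "break_indicator"))
  if (kind == "bilinear_loading" && (is.null(kappa) || length(kappa) != 1))
    stop_mrpop("a bilinear loading must name exactly one kappa series")
  if (kind == "break_indicator" && is.null(break_year))
    stop_mrpop("a break indicator needs a threshold year")
  list(name = name, dims = dims, kind = kind, prior = prior,
       kappa = kappa, group_dim = group_dim, break_year = break_year)
}

#' Define a latent time-effect (kappa) series
#'
#' The series is identified by fixing its value at the first observed period
#' to zero.  Dynamics:
#' * `ar1_drift`: `k_t ~ N(phi1 + phi2 * k_{t-1}, sigma^2)`, `phi2` in \[0,1\].
#' * `ar1_nodrift`: as above with `phi1 = 0`.
#' * `rw_drift`: `phi2 = 1` fixed (random walk with drift).
#' * `mrw_drift`: sex-paired bivariate random walk with drift vector
#'   `(phi11, phi12)` and covariance `Sigma = D Omega D` (marginal sds
#'   `sigma_M`, `sigma_F`; LKJ(2)-prior correlation).
#' * `var1_drift`: sex-paired VAR(1) with diagonal autoregression
#'   `(phi21, phi22)` and the same covariance decomposition.
#'
#' @param name series label.
#' @param dynamics one of the five above.
#' @return a kappa-spec list.
#' @export
kappa_spec <- function(name, dynamics) {
  dynamics <- match.arg(dynamics, c("ar1_drift", "ar1_nodrift", "rw_drift",
                                    "mrw_drift", "var1_drift"))
  list(name = name, dynamics = dynamics,
       sex_paired = dynamics %in% c("mrw_drift", "var1_drift"))
}

kappa_has_drift <- function(ks) ks$dynamics != "ar1_nodrift"
kappa_has_ar <- function(ks) ks$dynamics %in% c("ar1_drift", "ar1_nodrift", "var1_drift")

#' Default per-component model specifications
#'
#' Returns the reference log-bilinear specification for each demographic
#' component:
#'
#' * internal migration: `c + AS + OA + DA + OD1 + OD2*k1(t) + A1 + A2*k2(t)`
#'   with AR(1)-with-drift time effects, a symmetric prior linking opposite
#'   origin-destination flows, and five-year out-migration probabilities as
#'   the modelled scale;
#' * mortality: `c + RA + RS + AS1 + AS2*k(s,t)` with a sex-paired bivariate
#'   random walk with drift for `k` (no region-time bilinear term);
#' * fertility: `c + RA + A1 + A2*k1(t) + R1 + R2*k2(t)` with driftless
#'   AR(1) time effects (females only, reproductive ages);
#' * immigration / emigration: `c + R*1(year >= break) + RA + AS1 +
#'   AS2*k1(s,t) + R1 + R2*k2(t)` with a sex-paired VAR(1) for `k1` and an
#'   AR(1) with drift for `k2`; immigration models counts (exposure 1),
#'   emigration models rates.
#'
#' Priors: intercept Normal(0, variance 5); interactions Normal(0, 0.2^2);
#' main-effect profiles Normal(0, sigma^2) with sigma ~ half-t(2.5, 0.5);
#' constrained bilinear loadings summing to one; overdispersion sd sigma ~
#' half-t(2.5, 0.5).
#'
#' @param component component name.
#' @param break_year definition-change year for international migration
#'   (default 2004).
#' @return an object of class `mrpop_model_spec`.
#' @export
default_model_spec <- function(component, break_year = 2004) {
  component <- match.arg(component, COMPONENTS)
  ixn <- prior_normal(0, 0.2)
  main <- prior_hier_normal()
  icpt <- prior_normal(0, sqrt(5))
  spec <- switch(component,
    internal_migration = list(
      terms = list(
        model_term("c", kind = "intercept", prior = icpt),
        model_term("AS", c("age", "sex"), "interaction", ixn),
        model_term("OA", c("origin", "age"), "interaction", ixn),
        model_term("DA", c("destination", "age"), "interaction", ixn),
        model_term("OD1", "od", "main", prior_symmetric_od()),
        model_term("OD2", "od", "bilinear_loading",
                   prior_constrained_bilinear(), kappa = "kappa1"),
        model_term("A1", "age", "main", main),
        model_term("A2", "age", "bilinear_loading",
                   prior_constrained_bilinear(), kappa = "kappa2")),
      kappas = list(kappa_spec("kappa1", "ar1_drift"),
                    kappa_spec("kappa2", "ar1_drift"))),
    mortality = list(
      terms = list(
        model_term("c", kind = "intercept", prior = icpt),
        model_term("RA", c("region", "age"), "interaction", ixn),
        model_term("RS", c("region", "sex"), "interaction", ixn),
        model_term("AS1", c("age", "sex"), "main", main),
        model_term("AS2", "age", "bilinear_loading",
                   prior_constrained_bilinear(), kappa = "kappa",
                   group_dim = "sex")),
      kappas = list(kappa_spec("kappa", "mrw_drift"))),
    fertility = list(
      terms = list(
        model_term("c", kind = "intercept", prior = icpt),
        model_term("RA", c("region", "age"), "interaction", ixn),
        model_term("A1", "age", "main", main),
        model_term("A2", "age", "bilinear_loading",
                   prior_constrained_bilinear(), kappa = "kappa1"),
        model_term("R1", "region", "main", main),
        model_term("R2", "region", "bilinear_loading",
                   prior_constrained_bilinear(), kappa = "kappa2")),
      kappas = list(kappa_spec("kappa1", "ar1_nodrift"),
                    kappa_spec("kappa2", "ar1_nodrift"))),
    # immigration and emigration share one structure
    {
      list(
        terms = list(
          model_term("c", kind = "intercept", prior = icpt),
          model_term("Rbrk", "region", "break_indicator", main,
                     break_year = break_year),
          model_term("RA", c("region", "age"), "interaction", ixn),
          model_term("AS1", c("age", "sex"), "main", main),
          model_term("AS2", "age", "bilinear_loading",
                     prior_constrained_bilinear(), kappa = "kappa1",
                     group_dim = "sex"),
          model_term("R1", "region", "main", main),
          model_term("R2", "region", "bilinear_loading",
                     prior_constrained_bilinear(), kappa = "kappa2")),
        kappas = list(kappa_spec("kappa1", "var1_drift"),
                      kappa_spec("kappa2", "ar1_drift")))
    })
  structure(list(component = component, terms = spec$terms,
                 kappas = spec$kappas,
                 sigma_prior = prior_hier_normal()),
            class = "mrpop_model_spec")
}

#' @export
print.mrpop_model_spec <- function(x, ...) {
  bl <- vapply(x$terms, function(tm) tm$kind == "bilinear_loading", logical(1))
  lab <- vapply(x$terms, function(tm) {
    if (tm$kind == "bilinear_loading") paste0(tm$name, "*", tm$kappa)
    else if (tm$kind == "break_indicator") paste0(tm$name, "(t>=", tm$break_year, ")")
    else tm$name
  }, character(1))
  cat("<mrpop_model_spec>", x$component, "\n")
  cat("  log mu ~ N(", paste(lab, collapse = " + "), ", sigma^2 )\n")
  for (ks in x$kappas)
    cat("  ", ks$name, ":", ks$dynamics,
        if (ks$sex_paired) "(sex-paired)" else "", "\n")
  invisible(x)
}

#' Serialise / deserialise a model specification to YAML
#'
#' @param spec an `mrpop_model_spec`.
#' @param path file path.
#' @return `read_model_spec` returns an `mrpop_model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "mrpop_model_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$terms <- lapply(raw$terms, function(tm) {
    tm$dims <- as.character(tm$dims %||% character())
    tm
  })
  structure(raw, class = "mrpop_model_spec")
}
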