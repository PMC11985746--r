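# Log-linear model-selection harness.  Candidate specifications are
# simplified to plain Poisson log-linear GLMs (no bilinear terms, no latent
# overdispersion) and fitted by maximum likelihood with the log exposure as
# offset; candidates are ranked by the root-mean-square error of log-rate
# residuals and by the Schwarz (Bayes) information criterion.

# Build a model-frame data.frame of factors, one per candidate term.
selection_design <- function(spec, table) {
  cells <- table$cells
  reg <- table$registry
  df <- data.frame(.count = cells$count, .exposure = cells$exposure)
  vars <- character()
  for (tm in spec$terms) {
    if (tm$kind == "bilinear_loading")
      stop_mrpop("candidates for select_model must not contain bilinear terms")
    if (tm$kind == "intercept") next
    ti <- term_index(tm, cells, spec$component, reg)
    col <- factor(ti$labels[ti$idx], levels = ti$labels)
    if (tm$kind == "break_indicator")
      col <- factor(ifelse(cells$year >= tm$break_year,
                           as.character(col), ".pre"),
                    levels = c(".pre", ti$labels))
    df[[tm$name]] <- droplevels(col)
    vars <- c(vars, tm$name)
  }
  list(df = df, vars = vars)
}

#' Compare simplified log-linear candidate models
#'
#' Each candidate is fitted as a Poisson GLM with log link and offset
#' `log(exposure)`; interactions enter as single composite factors, which is
#' equivalent to the corresponding log-linear parameterisation.  RMSE is
#' computed on log-rate residuals `log(count / exposure) - fitted predictor`
#' over cells with positive counts (zero-count cells have no finite log
#' rate); BIC is `-2 logLik + p log(N)` with `N` the total number of cells.
#'
#' @param candidates named list of `mrpop_model_spec`s without bilinear
#'   terms (e.g. built with [model_term()]).
#' @param table a [component_table()].
#' @return data frame with one row per candidate: `rmse`, `bic`,
#'   `n_params`, `converged`, ordered as supplied.
#' @export
select_model <- function(candidates, table) {
  stopifnot(inherits(table, "mrpop_table"), length(candidates) >= 1)
  if (is.null(names(candidates)))
    names(candidates) <- paste0("m", seq_along(candidates))
  out <- lapply(names(candidates), function(nm) {
    spec <- candidates[[nm]]
    des <- selection_design(spec, table)
    rhs <- if (length(des$vars)) paste(des$vars, collapse = " + ") else "1"
    fml <- stats::as.formula(paste(".count ~", rhs, "+ offset(log(.exposure))"))
    fit <- suppressWarnings(stats::glm(fml, family = stats::poisson(),
                                       data = des$df))
    pos <- des$df$.count > 0
    eta <- fit$linear.predictors - log(des$df$.exposure)
    resid <- log(des$df$.count[pos] / des$df$.exposure[pos]) - eta[pos]
    p <- fit$rank
    N <- nrow(des$df)
    data.frame(candidate = nm,
               rmse = sqrt(mean(resid^2)),
               bic = -2 * as.numeric(stats::logLik(fit)) + p * log(N),
               n_params = p,
               converged = fit$converged)
  })
  do.call(rbind, out)
}

#' Build a simplified (log-linear only) candidate specification
#'
#' Convenience wrapper assembling an `mrpop_model_spec` from plain terms for
#' use with [select_model()]; priors are irrelevant for the ML fits and set
#' to defaults.
#'
#' @param component component name.
#' @param terms list of [model_term()]s (an intercept is added
#'   automatically).
#' @return an `mrpop_model_spec` with no kappa series.
#' @export
loglinear_candidate <- function(component, terms = list()) {
  component <- match.arg(component, COMPONENTS)
  structure(list(component = component,
                 terms = c(list(model_term("c", kind = "intercept",
                                           prior = prior_normal(0, sqrt(5)))),
                           terms),
                 kappas = list(),
                 sigma_prior = prior_hier_normal()),
            class = "mrpop_model_spec")
}
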