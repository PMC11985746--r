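# Posterior predictive forecasting of component rates/probabilities/counts:
# per draw, the latent time effects are simulated forward, the log-scale
# predictor is rebuilt for future cells with all non-time parameters held at
# their posterior values, lognormal overdispersion noise is added, and the
# result is exponentiated.  Poisson count variability is deliberately not
# simulated: forecast uncertainty reflects rate uncertainty only.

#' Forecast component rates from posterior draws
#'
#' @param draws an `mrpop_draws` object from [fit_component()].
#' @param horizon_years future observation times extending the fitted year
#'   grid (same step, starting one step after the last observed year).
#' @param seed RNG seed governing both the simulated kappa innovations and
#'   the lognormal noise.
#' @param subsample optional number of posterior draws to propagate
#'   (default: all, in order).
#' @return an object of class `mrpop_forecast`: future cell grid, a
#'   `draws x cells` matrix `mu` on the component's native scale
#'   (probability, rate or count), and the per-draw forecasted kappa paths.
#' @export
forecast_component <- function(draws, horizon_years, seed = 1,
                               subsample = NULL) {
  stopifnot(inherits(draws, "mrpop_draws"))
  reg <- draws$registry
  spec <- draws$spec
  horizon_years <- as.integer(horizon_years)
  step <- reg$year_step
  last <- reg$years[n_years(reg)]
  if (any(horizon_years != last + step * seq_along(horizon_years)))
    stop_mrpop("horizon_years must extend the observed grid (step %d after %d)",
               step, last)
  H <- length(horizon_years)
  reg_f <- registry_with_years(reg, horizon_years)
  cells <- component_cell_grid(spec$component, reg_f)
  frame_f <- build_frame(spec, cells, reg_f)
  idx <- seq_len(draws$n_draws)
  if (!is.null(subsample)) idx <- idx[seq_len(min(subsample, length(idx)))]
  B <- length(idx)
  mu <- matrix(NA_real_, B, nrow(cells))
  kap_paths <- vector("list", B)
  kmap <- stats::setNames(spec$kappas, vapply(spec$kappas, `[[`, "", "name"))
  set.seed(seed)
  for (b in seq_len(B)) {
    dr <- extract_draw(draws, idx[b], terms = frame_f$terms)
    state <- list(coef = list(), loading = list(), kappa = list())
    for (tm in frame_f$terms) {
      if (tm$kind == "bilinear_loading") {
        state$loading[[tm$name]] <- dr$params[[tm$name]]
      } else {
        state$coef[[tm$name]] <- dr$params[[tm$name]]
      }
    }
    kp <- list()
    for (kn in names(kmap)) {
      ks <- kmap[[kn]]
      kobs <- dr$kappa_values[[kn]]
      kobs <- if (is.matrix(kobs)) kobs else matrix(kobs, nrow = 1)
      lastk <- kobs[, ncol(kobs)]
      fut <- forecast_path(ks, dr$dynamics[[kn]], lastk, H)
      fut <- if (is.matrix(fut)) fut else matrix(fut, nrow = 1)
      state$kappa[[kn]] <- fut
      kp[[kn]] <- fut
    }
    M <- eval_predictor(frame_f, state)
    mu[b, ] <- exp(M + stats::rnorm(nrow(cells), 0, dr$sigma))
    kap_paths[[b]] <- kp
  }
  structure(list(component = spec$component, cells = cells, mu = mu,
                 years = horizon_years, registry = reg_f,
                 base_registry = reg, kappa_paths = kap_paths,
                 draw_index = idx),
            class = "mrpop_forecast")
}

#' @export
print.mrpop_forecast <- function(x, ...) {
  cat("<mrpop_forecast>", x$component, "-", nrow(x$mu), "draws x",
      ncol(x$mu), "cells, years", paste(range(x$years), collapse = "-"), "\n")
  invisible(x)
}

#' Quantile summary of a component forecast
#'
#' @param forecast an `mrpop_forecast`.
#' @param probs quantile probabilities.
#' @return long data frame: cell keys plus one column per quantile.
#' @export
summarize_forecast <- function(forecast,
                               probs = c(0.025, 0.1, 0.25, 0.5, 0.75, 0.9, 0.975)) {
  qs <- t(apply(forecast$mu, 2, mrpop_quantile, probs = probs))
  colnames(qs) <- paste0("q", probs * 100)
  cbind(forecast$cells, as.data.frame(qs))
}

#' Persist / load a forecast as long CSV
#'
#' Columns `draw, origin, destination, age, sex, year, value`.
#' @param forecast an `mrpop_forecast`.
#' @param path CSV path.
#' @export
write_forecast <- function(forecast, path) {
  B <- nrow(forecast$mu)
  cells <- forecast$cells
  out <- data.frame(
    component = forecast$component,
    draw = rep(seq_len(B), each = nrow(cells)),
    origin = rep(cells$origin, B),
    destination = rep(ifelse(is.na(cells$destination), "", cells$destination), B),
    age = rep(cells$age, B),
    sex = rep(ifelse(is.na(cells$sex), "", cells$sex), B),
    year = rep(cells$year, B),
    value = as.vector(t(forecast$mu)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
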