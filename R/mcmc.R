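# Metropolis-within-Gibbs sampler for the Poisson-lognormal log-bilinear
# component models.  Conditional on the latent per-cell log rates, every
# linear effect, bilinear loading and kappa path has an exact Gaussian full
# conditional (the augmented likelihood is Gaussian in them), so those
# blocks are true Gibbs updates.  The latent log rates use a vectorised
# Metropolis step with curvature-matched proposal scales, and scale /
# correlation parameters use univariate slice sampling.

#' MCMC configuration
#'
#' @param chains number of chains (run sequentially).
#' @param warmup discarded sweeps per chain.
#' @param samples retained sweeps per chain.
#' @param seed base RNG seed; chain `i` uses `seed + i - 1`.
#' @param target_accept nominal acceptance target for the latent-rate
#'   Metropolis step (informational; the proposal scale is curvature-based).
#' @return an `mrpop_mcmc_config` list.
#' @export
mcmc_config <- function(chains = 2, warmup = 500, samples = 500, seed = 1,
                        target_accept = 0.6) {
  stopifnot(chains >= 1, warmup >= 0, samples >= 1, target_accept > 0)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 samples = as.integer(samples), seed = as.integer(seed),
                 target_accept = target_accept),
            class = "mrpop_mcmc_config")
}

# Sum x within integer groups 1..L (missing groups give 0).
sum_by <- function(x, idx, L) {
  out <- numeric(L)
  tmp <- rowsum(x, idx)
  out[as.integer(rownames(tmp))] <- tmp
  out
}

count_by <- function(idx, L) tabulate(idx, nbins = L)

half_t_median <- function(df, scale) scale * stats::qt(0.75, df)

# ---- state initialisation ---------------------------------------------------

init_state <- function(frame, spec) {
  state <- list(coef = list(), loading = list(), kappa = list(), dyn = list(),
                hier_sd = list())
  for (tm in frame$terms) {
    if (tm$kind == "bilinear_loading") {
      state$loading[[tm$name]] <- matrix(1 / tm$L, tm$n_groups, tm$L)
    } else {
      state$coef[[tm$name]] <- numeric(tm$L)
      if (tm$prior$family == "normal_hier_sd_half_t")
        state$hier_sd[[tm$name]] <- half_t_median(tm$prior$df, tm$prior$scale)
      if (tm$prior$family == "symmetric_od_normal") {
        nup <- nrow(unordered_pairs(frame$registry$regions))
        state$od_alpha <- numeric(nup)
        state$od_sigma <- half_t_median(tm$prior$df, tm$prior$scale)
      }
    }
  }
  for (ks in spec$kappas) {
    S <- if (ks$sex_paired) 2L else 1L
    state$kappa[[ks$name]] <- matrix(0, S, n_years(frame$registry))
    state$dyn[[ks$name]] <- if (ks$sex_paired) {
      list(phi1 = c(0, 0),
           phi2 = if (ks$dynamics == "var1_drift") c(0.5, 0.5) else c(1, 1),
           sigma_M = 0.1, sigma_F = 0.1, rho = 0)
    } else {
      list(phi1 = 0, phi2 = switch(ks$dynamics, rw_drift = 1, 0.5),
           sigma = 0.1)
    }
  }
  state$sigma <- half_t_median(spec$sigma_prior$df, spec$sigma_prior$scale)
  Y <- frame$cells$count
  K <- frame$cells$exposure
  state$lm <- log((Y + 0.5) / K)
  state
}

# ---- latent log rates -------------------------------------------------------

update_lm <- function(state, frame, M) {
  Y <- frame$cells$count
  K <- frame$cells$exposure
  lm0 <- state$lm
  curv <- Y + 1 / state$sigma^2
  sd_prop <- 1.7 / sqrt(curv)
  lm1 <- lm0 + stats::rnorm(frame$n, 0, sd_prop)
  logr <- (Y * lm1 - K * exp(lm1) - (lm1 - M)^2 / (2 * state$sigma^2)) -
          (Y * lm0 - K * exp(lm0) - (lm0 - M)^2 / (2 * state$sigma^2))
  acc <- log(stats::runif(frame$n)) < logr
  state$lm <- ifelse(acc, lm1, lm0)
  state$accept_lm <- mean(acc)
  state
}

update_sigma <- function(state, frame, M, prior) {
  r <- state$lm - M
  n <- length(r)
  ss <- sum(r^2)
  logf <- function(s) {
    if (s <= 0) return(-Inf)
    -n * log(s) - ss / (2 * s^2) + dhalf_t(s, prior$df, prior$scale)
  }
  state$sigma <- slice_sample1(state$sigma, logf, w = 0.2, lower = 1e-8)
  state
}

# ---- linear terms -----------------------------------------------------------

# Gibbs update of one linear-in-parameters term (intercept, main,
# interaction, break indicator, or the symmetric-prior OD1 term).
update_linear_term <- function(state, frame, tm, M) {
  contrib <- term_contribution(tm, state, frame)
  r <- state$lm - M + contrib
  keep <- tm$active %||% TRUE
  idx <- tm$idx
  if (!isTRUE(keep)) {
    idx <- idx[keep]
    rr <- r[keep]
  } else rr <- r
  s2 <- state$sigma^2
  nl <- count_by(idx, tm$L)
  sl <- sum_by(rr, idx, tm$L)
  pr <- tm$prior
  if (pr$family == "normal_fixed_sd") {
    m0 <- rep(pr$mean, tm$L); v0 <- pr$sd^2
  } else if (pr$family == "normal_hier_sd_half_t") {
    m0 <- numeric(tm$L); v0 <- state$hier_sd[[tm$name]]^2
  } else if (pr$family == "symmetric_od_normal") {
    m0 <- state$od_alpha[od_to_unordered(frame$registry$regions)]
    v0 <- state$od_sigma^2
  } else stop_mrpop("unsupported prior for term '%s'", tm$name)
  post_prec <- nl / s2 + 1 / v0
  post_mean <- (sl / s2 + m0 / v0) / post_prec
  state$coef[[tm$name]] <- stats::rnorm(tm$L, post_mean, sqrt(1 / post_prec))

  # hyper-parameter updates
  if (pr$family == "normal_hier_sd_half_t") {
    co <- state$coef[[tm$name]]
    ssc <- sum(co^2); L <- tm$L
    logf <- function(s) {
      if (s <= 0) return(-Inf)
      -L * log(s) - ssc / (2 * s^2) + dhalf_t(s, pr$df, pr$scale)
    }
    state$hier_sd[[tm$name]] <- slice_sample1(state$hier_sd[[tm$name]], logf,
                                              w = 0.3, lower = 1e-8)
  }
  if (pr$family == "symmetric_od_normal") {
    co <- state$coef[[tm$name]]
    u2 <- od_to_unordered(frame$registry$regions)
    nup <- max(u2)
    ssum <- sum_by(co, u2, nup)      # each unordered pair has 2 ordered obs
    prec <- 2 / state$od_sigma^2 + 1 / pr$alpha_sd^2
    mean_ <- (ssum / state$od_sigma^2) / prec
    state$od_alpha <- stats::rnorm(nup, mean_, sqrt(1 / prec))
    mu <- state$od_alpha[u2]
    ssr <- sum((co - mu)^2); Lod <- length(co)
    logf <- function(s) {
      if (s <= 0) return(-Inf)
      -Lod * log(s) - ssr / (2 * s^2) + dhalf_t(s, pr$df, pr$scale)
    }
    state$od_sigma <- slice_sample1(state$od_sigma, logf, w = 0.3, lower = 1e-8)
  }
  state
}

# ---- recentring (interweaving) moves ---------------------------------------

# The likelihood is invariant under shifting a level-mean of one term into a
# coarser term that covers the same cells (e.g. the age-means of an
# age-by-sex interaction into the age main effect, or any term's global mean
# into the intercept).  Sampling those shift directions from their exact
# Gaussian full conditionals (driven by the priors alone) removes the slow
# random-walk mixing of softly identified level parameters.

# Decompose a term's level index into the level of one of its dims.
term_dim_group <- function(tm_spec, term, dim, component, registry) {
  dims <- tm_spec$dims
  sizes <- vapply(dims, function(d)
    length(dim_levels(d, component, registry)), 0L)
  k <- match(dim, dims)
  idx <- seq_len(term$L) - 1L
  before <- if (k > 1) prod(sizes[1:(k - 1)]) else 1L
  (idx %/% before) %% sizes[k] + 1L
}

# Plan: list of moves (from term, to term or "c", per-level group vectors).
build_shift_plan <- function(frame, spec) {
  tspecs <- stats::setNames(spec$terms, vapply(spec$terms, `[[`, "", "name"))
  linear <- Filter(function(tm)
    tm$kind %in% c("main", "interaction") ||
      (tm$kind == "intercept"), frame$terms)
  has_c <- any(vapply(frame$terms, function(tm) tm$kind == "intercept", TRUE))
  plan <- list()
  for (tm in frame$terms) {
    if (!tm$kind %in% c("main", "interaction")) next
    ts <- tspecs[[tm$name]]
    if (has_c)
      plan[[length(plan) + 1]] <- list(from = tm$name, to = "c",
                                       gFrom = rep.int(1L, tm$L),
                                       gTo = 1L, n_levels = 1L)
    for (d in ts$dims) {
      for (um in frame$terms) {
        if (um$name == tm$name || !um$kind %in% c("main", "interaction")) next
        us <- tspecs[[um$name]]
        if (!d %in% us$dims || length(us$dims) > length(ts$dims)) next
        nl <- length(dim_levels(d, frame$component, frame$registry))
        plan[[length(plan) + 1]] <- list(
          from = tm$name, to = um$name,
          gFrom = term_dim_group(ts, tm, d, frame$component, frame$registry),
          gTo = term_dim_group(us, um, d, frame$component, frame$registry),
          n_levels = nl)
      }
    }
  }
  plan
}

prior_moments <- function(tm, state, frame) {
  pr <- tm$prior
  if (tm$kind == "intercept")
    return(list(m0 = pr$mean, v = pr$sd^2))
  switch(pr$family,
    normal_fixed_sd = list(m0 = rep(pr$mean, tm$L), v = pr$sd^2),
    normal_hier_sd_half_t = list(m0 = numeric(tm$L),
                                 v = state$hier_sd[[tm$name]]^2),
    symmetric_od_normal = list(
      m0 = state$od_alpha[od_to_unordered(frame$registry$regions)],
      v = state$od_sigma^2),
    stop_mrpop("unsupported prior in shift move"))
}

update_shifts <- function(state, frame, plan) {
  for (mv in plan) {
    tmF <- frame$terms[[mv$from]]
    tmT <- frame$terms[[mv$to]]
    pF <- prior_moments(tmF, state, frame)
    pT <- prior_moments(tmT, state, frame)
    coefF <- state$coef[[mv$from]]
    coefT <- state$coef[[mv$to]]
    nF <- count_by(mv$gFrom, mv$n_levels)
    nT <- count_by(mv$gTo, mv$n_levels)
    sF <- sum_by(coefF - pF$m0, mv$gFrom, mv$n_levels)
    sT <- sum_by(coefT - pT$m0, mv$gTo, mv$n_levels)
    prec <- nF / pF$v + nT / pT$v
    mean_ <- (sF / pF$v - sT / pT$v) / prec
    delta <- stats::rnorm(mv$n_levels, mean_, sqrt(1 / prec))
    state$coef[[mv$from]] <- coefF - delta[mv$gFrom]
    state$coef[[mv$to]] <- coefT + delta[mv$gTo]
  }
  state
}

# ---- bilinear loadings ------------------------------------------------------

# Exact Gaussian update of the free loading values of one group of a
# constrained bilinear term (full conditional given kappa and the latents).
update_loading <- function(state, frame, tm, M) {
  s2 <- state$sigma^2
  contrib <- term_contribution(tm, state, frame)
  r_all <- state$lm - M + contrib
  kap <- state$kappa[[tm$kappa]]
  kcell <- kap[cbind(tm$ksex, frame$tidx)]
  L <- tm$L
  P0 <- bilinear_prior_precision(L)
  m0 <- rep(1 / L, L - 1)
  for (g in seq_len(tm$n_groups)) {
    in_g <- tm$gidx == g
    lvl <- tm$idx[in_g]
    k <- kcell[in_g]
    r <- r_all[in_g]
    is_last <- lvl == L
    sl_k2 <- sum_by(k[!is_last]^2, lvl[!is_last], L)[seq_len(L - 1)]
    sl_kr <- sum_by(k[!is_last] * r[!is_last], lvl[!is_last], L)[seq_len(L - 1)]
    S_L <- sum(k[is_last]^2)
    SzR <- sum(k[is_last] * (r[is_last] - k[is_last]))
    Q <- (diag(sl_k2, nrow = L - 1) + S_L) / s2 + P0
    b <- (sl_kr - SzR) / s2 + P0 %*% m0
    u <- rmvnorm_precision(drop(b), Q)
    state$loading[[tm$name]][g, ] <- constrain_bilinear_loadings(u)
  }
  state
}

# ---- kappa paths ------------------------------------------------------------

# Exact Gaussian update of the free kappa values (t = 2..T) of one series,
# combining the time-series prior with the Gaussian likelihood through the
# bilinear loading.  `tm` is the (single) loading term using the series.
update_kappa <- function(state, frame, tm, ks, M) {
  s2 <- state$sigma^2
  T <- ncol(state$kappa[[ks$name]])
  m <- T - 1L
  if (m < 1) return(state)
  contrib <- term_contribution(tm, state, frame)
  r <- state$lm - M + contrib
  load <- state$loading[[tm$name]]
  a <- load[cbind(tm$gidx, tm$idx)]
  dyn <- state$dyn[[ks$name]]
  if (!ks$sex_paired) {
    Q <- matrix(0, m, m)
    b <- numeric(m)
    phi1 <- if (kappa_has_drift(ks)) dyn$phi1 else 0
    phi2 <- dyn$phi2
    sk2 <- dyn$sigma^2
    for (t in 2:T) {
      p <- t - 1L
      Q[p, p] <- Q[p, p] + 1 / sk2
      if (t >= 3) {
        q <- p - 1L
        Q[q, q] <- Q[q, q] + phi2^2 / sk2
        Q[p, q] <- Q[p, q] - phi2 / sk2
        Q[q, p] <- Q[q, p] - phi2 / sk2
        b[q] <- b[q] - phi1 * phi2 / sk2
      }
      b[p] <- b[p] + phi1 / sk2
    }
    sel <- frame$tidx >= 2
    lp <- sum_by(a[sel]^2, frame$tidx[sel] - 1L, m) / s2
    lb <- sum_by(a[sel] * r[sel], frame$tidx[sel] - 1L, m) / s2
    Q <- Q + diag(lp, nrow = m)
    b <- b + lb
    v <- rmvnorm_precision(b, Q)
    state$kappa[[ks$name]][1, ] <- c(0, v)
  } else {
    Sigma <- cov_from_corr(matrix(c(1, dyn$rho, dyn$rho, 1), 2, 2),
                           c(dyn$sigma_M, dyn$sigma_F))
    Qi <- solve(Sigma)
    ar <- dyn$phi2
    drift <- dyn$phi1
    nv <- 2L * m
    Q <- matrix(0, nv, nv)
    b <- numeric(nv)
    pos <- function(s, t) (s - 1L) * m + (t - 1L)  # t >= 2
    for (t in 2:T) {
      # e_s = v[pos(s,t)] - ar_s * v[pos(s,t-1)] - drift_s  (t-1 term absent at t=2)
      vars <- c(pos(1, t), pos(2, t))
      A <- diag(2)
      if (t >= 3) {
        vars <- c(vars, pos(1, t - 1), pos(2, t - 1))
        A <- cbind(A, diag(-ar, 2))
      }
      Q[vars, vars] <- Q[vars, vars] + t(A) %*% Qi %*% A
      b[vars] <- b[vars] + drop(t(A) %*% Qi %*% drift)
    }
    for (s in 1:2) {
      sel <- frame$tidx >= 2 & tm$ksex == s
      lp <- sum_by(a[sel]^2, frame$tidx[sel] - 1L, m) / s2
      lb <- sum_by(a[sel] * r[sel], frame$tidx[sel] - 1L, m) / s2
      ii <- pos(s, 2:T)
      Q[cbind(ii, ii)] <- Q[cbind(ii, ii)] + lp
      b[ii] <- b[ii] + lb
    }
    v <- rmvnorm_precision(b, Q)
    state$kappa[[ks$name]][1, ] <- c(0, v[seq_len(m)])
    state$kappa[[ks$name]][2, ] <- c(0, v[m + seq_len(m)])
  }
  state
}

# ---- dynamics parameters ----------------------------------------------------

update_dynamics <- function(state, ks) {
  dyn <- state$dyn[[ks$name]]
  kap <- state$kappa[[ks$name]]
  T <- ncol(kap)
  if (!ks$sex_paired) {
    k <- kap[1, ]
    prev <- k[-T]; cur <- k[-1]
    if (kappa_has_drift(ks) && ks$dynamics != "ar1_nodrift") {
      d <- cur - dyn$phi2 * prev
      prec <- (T - 1) / dyn$sigma^2 + 1 / 4
      mean_ <- sum(d) / dyn$sigma^2 / prec
      dyn$phi1 <- stats::rnorm(1, mean_, sqrt(1 / prec))
    }
    if (kappa_has_ar(ks)) {
      z <- cur - dyn$phi1
      sxx <- sum(prev^2); sxy <- sum(prev * z)
      prec <- sxx / dyn$sigma^2 + 1 / 0.04
      mean_ <- (sxy / dyn$sigma^2 + 0.5 / 0.04) / prec
      dyn$phi2 <- rtruncnorm1(mean_, sqrt(1 / prec), 0, 1)
    }
    resid <- cur - dyn$phi1 - dyn$phi2 * prev
    nn <- T - 1; ssr <- sum(resid^2)
    logf <- function(s) {
      if (s <= 0) return(-Inf)
      -nn * log(s) - ssr / (2 * s^2) + stats::dnorm(s, 0, 1, log = TRUE) + log(2)
    }
    dyn$sigma <- slice_sample1(dyn$sigma, logf, w = 0.2, lower = 1e-8)
  } else {
    has_ar <- ks$dynamics == "var1_drift"
    emat <- function(d) {
      rbind(kap[1, -1] - d$phi1[1] - d$phi2[1] * kap[1, -T],
            kap[2, -1] - d$phi1[2] - d$phi2[2] * kap[2, -T])
    }
    sig2 <- function(d) cov_from_corr(matrix(c(1, d$rho, d$rho, 1), 2, 2),
                                      c(d$sigma_M, d$sigma_F))
    Qi <- solve(sig2(dyn))
    for (s in 1:2) {
      o <- 3 - s
      # drift phi1[s]: e_s = a_t - phi1_s with a_t = k_st - phi2_s k_{s,t-1}
      a <- kap[s, -1] - dyn$phi2[s] * kap[s, -T]
      eo <- kap[o, -1] - dyn$phi1[o] - dyn$phi2[o] * kap[o, -T]
      prec <- (T - 1) * Qi[s, s] + 1 / 4
      mean_ <- sum(Qi[s, s] * a + Qi[s, o] * eo) / prec
      dyn$phi1[s] <- stats::rnorm(1, mean_, sqrt(1 / prec))
      if (has_ar) {
        aa <- kap[s, -1] - dyn$phi1[s]
        bb <- kap[s, -T]
        eo <- kap[o, -1] - dyn$phi1[o] - dyn$phi2[o] * kap[o, -T]
        prec <- Qi[s, s] * sum(bb^2) + 1 / 0.04
        mean_ <- (sum(bb * (Qi[s, s] * aa + Qi[s, o] * eo)) + 0.5 / 0.04) / prec
        dyn$phi2[s] <- rtruncnorm1(mean_, sqrt(1 / prec), 0, 1)
      }
    }
    biv_loglik <- function(d) {
      S <- sig2(d)
      Qi <- solve(S)
      e <- emat(d)
      -0.5 * ((T - 1) * determinant(S)$modulus) -
        0.5 * sum(apply(e, 2, function(v) drop(crossprod(v, Qi %*% v))))
    }
    for (nm in c("sigma_M", "sigma_F")) {
      logf <- function(s) {
        if (s <= 0) return(-Inf)
        d <- dyn; d[[nm]] <- s
        as.numeric(biv_loglik(d)) + stats::dnorm(s, 0, 1, log = TRUE) + log(2)
      }
      dyn[[nm]] <- slice_sample1(dyn[[nm]], logf, w = 0.2, lower = 1e-8)
    }
    logf_rho <- function(r) {
      if (abs(r) >= 0.999) return(-Inf)
      d <- dyn; d$rho <- r
      as.numeric(biv_loglik(d)) + log(1 - r^2)   # LKJ(2) kernel
    }
    dyn$rho <- slice_sample1(dyn$rho, logf_rho, w = 0.3,
                             lower = -0.999, upper = 0.999)
  }
  state$dyn[[ks$name]] <- dyn
  state
}

# ---- one full sweep ---------------------------------------------------------

gibbs_sweep <- function(state, frame, spec, shift_plan = list()) {
  M <- eval_predictor(frame, state)
  state <- update_lm(state, frame, M)
  state <- update_sigma(state, frame, M, spec$sigma_prior)
  for (tm in frame$terms) {
    if (tm$kind == "bilinear_loading") next
    old <- term_contribution(tm, state, frame)
    state <- update_linear_term(state, frame, tm, M)
    M <- M - old + term_contribution(tm, state, frame)
  }
  state <- update_shifts(state, frame, shift_plan)
  kmap <- stats::setNames(spec$kappas, vapply(spec$kappas, `[[`, "", "name"))
  # the loading / kappa / dynamics blocks are mutually correlated along the
  # bilinear ridge; cycling them a few times per sweep decorrelates cheaply
  for (cycle in 1:3) {
    for (tm in frame$terms) {
      if (tm$kind != "bilinear_loading") next
      old <- term_contribution(tm, state, frame)
      state <- update_loading(state, frame, tm, M)
      M <- M - old + term_contribution(tm, state, frame)
      ks <- kmap[[tm$kappa]]
      old <- term_contribution(tm, state, frame)
      state <- update_kappa(state, frame, tm, ks, M)
      M <- M - old + term_contribution(tm, state, frame)
      state <- update_dynamics(state, ks)
    }
  }
  state
}

# ---- draw flattening --------------------------------------------------------

draw_layout <- function(frame, spec) {
  nm <- character()
  for (tm in frame$terms) {
    if (tm$kind == "bilinear_loading") {
      for (g in seq_len(tm$n_groups)) {
        pre <- if (nzchar(tm$group_labels[g])) paste0(tm$group_labels[g], ",") else ""
        nm <- c(nm, paste0(tm$name, "[", pre, tm$labels, "]"))
      }
    } else {
      nm <- c(nm, if (tm$L == 1) tm$name else paste0(tm$name, "[", tm$labels, "]"))
      if (tm$prior$family == "normal_hier_sd_half_t")
        nm <- c(nm, paste0("sd_", tm$name))
      if (tm$prior$family == "symmetric_od_normal") {
        up <- unordered_pairs(frame$registry$regions)
        nm <- c(nm, paste0("alpha[", up$a, ":", up$b, "]"), "sigma_OD")
      }
    }
  }
  yrs <- frame$registry$years
  for (ks in spec$kappas) {
    if (ks$sex_paired) {
      for (s in frame$registry$sexes)
        nm <- c(nm, paste0(ks$name, "[", s, ",", yrs, "]"))
      nm <- c(nm, paste0(ks$name, ".", c("phi11", "phi12")))
      if (ks$dynamics == "var1_drift")
        nm <- c(nm, paste0(ks$name, ".", c("phi21", "phi22")))
      nm <- c(nm, paste0(ks$name, ".", c("sigma_M", "sigma_F", "rho")))
    } else {
      nm <- c(nm, paste0(ks$name, "[", yrs, "]"))
      if (kappa_has_drift(ks) && ks$dynamics != "ar1_nodrift")
        nm <- c(nm, paste0(ks$name, ".phi1"))
      if (kappa_has_ar(ks)) nm <- c(nm, paste0(ks$name, ".phi2"))
      nm <- c(nm, paste0(ks$name, ".sigma"))
    }
  }
  c(nm, "sigma")
}

flatten_state <- function(state, frame, spec) {
  out <- numeric()
  for (tm in frame$terms) {
    if (tm$kind == "bilinear_loading") {
      out <- c(out, as.vector(t(state$loading[[tm$name]])))
    } else {
      out <- c(out, state$coef[[tm$name]])
      if (tm$prior$family == "normal_hier_sd_half_t")
        out <- c(out, state$hier_sd[[tm$name]])
      if (tm$prior$family == "symmetric_od_normal")
        out <- c(out, state$od_alpha, state$od_sigma)
    }
  }
  for (ks in spec$kappas) {
    kap <- state$kappa[[ks$name]]
    dyn <- state$dyn[[ks$name]]
    if (ks$sex_paired) {
      out <- c(out, kap[1, ], kap[2, ], dyn$phi1)
      if (ks$dynamics == "var1_drift") out <- c(out, dyn$phi2)
      out <- c(out, dyn$sigma_M, dyn$sigma_F, dyn$rho)
    } else {
      out <- c(out, kap[1, ])
      if (kappa_has_drift(ks) && ks$dynamics != "ar1_nodrift")
        out <- c(out, dyn$phi1)
      if (kappa_has_ar(ks)) out <- c(out, dyn$phi2)
      out <- c(out, dyn$sigma)
    }
  }
  c(out, state$sigma)
}

# ---- main fitting entry point ----------------------------------------------

#' Fit a log-bilinear component model by MCMC
#'
#' Runs the Metropolis-within-Gibbs sampler on the Poisson-lognormal
#' log-bilinear model defined by `spec` for the counts in `table`.  All hard
#' constraints (first-period kappa fixed at zero, sum-to-one bilinear
#' loadings, symmetric origin-destination prior means) hold exactly in every
#' draw by construction.
#'
#' @param spec an [default_model_spec()] (or customised) specification whose
#'   component matches the table.
#' @param table a [component_table()].
#' @param cfg an [mcmc_config()].
#' @return an object of class `mrpop_draws`: a draws matrix
#'   (`chains * samples` rows, named parameters), per-parameter split-Rhat
#'   and effective-sample-size diagnostics, warning records for parameters
#'   with split-Rhat above 1.01, and the mean latent-rate Metropolis
#'   acceptance per chain.
#' @export
fit_component <- function(spec, table, cfg = mcmc_config()) {
  stopifnot(inherits(spec, "mrpop_model_spec"), inherits(table, "mrpop_table"))
  if (spec$component != table$component)
    stop_mrpop("spec is for '%s' but table is '%s'", spec$component,
               table$component)
  frame <- build_frame(spec, table$cells, table$registry)
  shift_plan <- build_shift_plan(frame, spec)
  layout <- draw_layout(frame, spec)
  P <- length(layout)
  draws <- array(NA_real_, c(cfg$samples, cfg$chains, P))
  accept <- numeric(cfg$chains)
  for (ch in seq_len(cfg$chains)) {
    set.seed(cfg$seed + ch - 1L)
    state <- init_state(frame, spec)
    acc <- 0
    M0 <- eval_predictor(frame, state)
    if (!all(is.finite(M0))) stop_mrpop("non-finite predictor at initialisation")
    for (it in seq_len(cfg$warmup + cfg$samples)) {
      state <- gibbs_sweep(state, frame, spec, shift_plan)
      if (it > cfg$warmup) {
        draws[it - cfg$warmup, ch, ] <- flatten_state(state, frame, spec)
        acc <- acc + state$accept_lm
      }
    }
    accept[ch] <- acc / cfg$samples
  }
  flat <- matrix(aperm(draws, c(1, 2, 3)), cfg$samples * cfg$chains, P)
  colnames(flat) <- layout
  const <- apply(flat, 2, function(v) max(v) - min(v) < 1e-12)
  rhat <- ess <- rep(NA_real_, P)
  for (p in which(!const)) {
    rhat[p] <- split_rhat(draws[, , p])
    ess[p] <- ess_basic(draws[, , p])
  }
  diagnostics <- data.frame(parameter = layout, rhat = rhat, ess = ess)
  bad <- diagnostics$parameter[!is.na(rhat) & rhat > 1.01]
  warn <- if (length(bad))
    sprintf("split-Rhat > 1.01 for %d parameter(s): %s", length(bad),
            paste(utils::head(bad, 5), collapse = ", "))
  else character()
  structure(list(draws = flat, spec = spec, registry = table$registry,
                 component = spec$component, config = cfg,
                 diagnostics = diagnostics, warnings = warn,
                 accept_lm = accept,
                 n_draws = nrow(flat)),
            class = "mrpop_draws")
}

#' @export
print.mrpop_draws <- function(x, ...) {
  cat("<mrpop_draws>", x$component, "-", x$n_draws, "draws (",
      x$config$chains, "chains x", x$config$samples, "samples )\n")
  ok <- stats::na.omit(x$diagnostics$rhat)
  if (length(ok)) cat("  max split-Rhat:", round(max(ok), 3), "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# Extract one draw as a (params, kappa_values) pair usable by
# linear_predictor() / forecast machinery.
extract_draw <- function(draws_obj, i, terms = NULL) {
  v <- draws_obj$draws[i, ]
  spec <- draws_obj$spec
  reg <- draws_obj$registry
  frame_terms <- terms %||% build_frame(spec,
                                        component_cell_grid(spec$component, reg),
                                        reg)$terms
  params <- list()
  for (tm in frame_terms) {
    if (tm$kind == "bilinear_loading") {
      m <- matrix(NA_real_, tm$n_groups, tm$L)
      for (g in seq_len(tm$n_groups)) {
        pre <- if (nzchar(tm$group_labels[g])) paste0(tm$group_labels[g], ",") else ""
        m[g, ] <- v[paste0(tm$name, "[", pre, tm$labels, "]")]
      }
      params[[tm$name]] <- m
    } else {
      nms <- if (tm$L == 1) tm$name else paste0(tm$name, "[", tm$labels, "]")
      params[[tm$name]] <- unname(v[nms])
    }
  }
  kappa_values <- list()
  dyn <- list()
  yrs <- reg$years
  for (ks in spec$kappas) {
    if (ks$sex_paired) {
      kappa_values[[ks$name]] <- rbind(
        v[paste0(ks$name, "[", reg$sexes[1], ",", yrs, "]")],
        v[paste0(ks$name, "[", reg$sexes[2], ",", yrs, "]")])
      d <- list(phi1 = unname(v[paste0(ks$name, ".", c("phi11", "phi12"))]))
      d$phi2 <- if (ks$dynamics == "var1_drift")
        unname(v[paste0(ks$name, ".", c("phi21", "phi22"))]) else c(1, 1)
      d$sigma_M <- unname(v[paste0(ks$name, ".sigma_M")])
      d$sigma_F <- unname(v[paste0(ks$name, ".sigma_F")])
      d$rho <- unname(v[paste0(ks$name, ".rho")])
      dyn[[ks$name]] <- d
    } else {
      kappa_values[[ks$name]] <- unname(v[paste0(ks$name, "[", yrs, "]")])
      d <- list(
        phi1 = if (kappa_has_drift(ks) && ks$dynamics != "ar1_nodrift")
          unname(v[paste0(ks$name, ".phi1")]) else 0,
        phi2 = if (kappa_has_ar(ks)) unname(v[paste0(ks$name, ".phi2")])
               else 1,
        sigma = unname(v[paste0(ks$name, ".sigma")]))
      dyn[[ks$name]] <- d
    }
  }
  list(params = params, kappa_values = kappa_values, dynamics = dyn,
       sigma = unname(v["sigma"]))
}
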