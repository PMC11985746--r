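---
title: "Probabilistic multiregional population forecasting with mrpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic multiregional population forecasting with mrpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Subnational population forecasts must reconcile five interacting flows —
interregional migration, mortality, fertility, immigration and emigration —
while quantifying how uncertain the resulting population counts are.
`mrpop` implements a unified Bayesian treatment: every component is a
cross-classified count table modelled with the same Poisson–lognormal
log-bilinear family, the latent time indices of those models are forecast
with simple time-series processes, and posterior draws of the component
forecasts are pushed through a deterministic multiregional cohort-component
engine, yielding a full predictive distribution of population by region,
age group and sex.

## The component model

For a count $Y$ in cell $(r, x, s, t)$ (region or origin–destination pair,
five-year age group, sex, time) with exposure $K$,

$$Y \sim \mathrm{Poisson}(\mu K), \qquad
  \log \mu \sim \mathrm{Normal}(\mathcal{M}, \sigma^2),$$

where $\sigma^2$ allows overdispersion beyond Poisson variability and
$\mathcal{M}$ is an additive log-linear predictor carrying bilinear
(Lee–Carter-type) terms.  The per-component default predictors are:

* **internal migration** (five-year transition probabilities, origin
  population five years earlier as exposure):
  $c + AS + OA + DA + OD_1 + OD_2\,\kappa_{1t} + A_1 + A_2\,\kappa_{2t}$,
  with a symmetric prior linking the origin–destination level of a flow and
  its reverse flow;
* **mortality** (annual rates, mid-year population exposure):
  $c + RA + RS + AS_1 + AS_2\,\kappa_{st}$ with one time index per sex and
  no region–time bilinear term, so rates change at a common pace across
  regions while sexes may diverge;
* **fertility** (annual rates, female mid-year population, reproductive
  ages 15–49): $c + RA + A_1 + A_2\,\kappa_{1t} + R_1 + R_2\,\kappa_{2t}$;
* **immigration** (annual counts, exposure $\equiv 1$) and **emigration**
  (annual rates): $c + R\,\mathbf{1}(t \ge t_0) + RA + AS_1 +
  AS_2\,\kappa_{1st} + R_1 + R_2\,\kappa_{2t}$, where the region-specific
  indicator absorbs a definition change in the migration statistics from a
  threshold year (2004 by default).

Latent time indices follow, per component: AR(1) with drift (internal
migration, and the regional index of international migration), a sex-paired
bivariate random walk with drift (mortality), driftless AR(1) (fertility,
so forecast rates stay level instead of trending), and a sex-paired VAR(1)
with diagonal autoregression (international migration age indices).
Bivariate innovation covariances are parameterised as
$\Sigma = D\,\Omega\,D$ with marginal standard deviations on the diagonal
of $D$ and an LKJ(2) prior on the correlation $\Omega$.  One source text we
relied on prints this decomposition as $D^{-1}\Omega D^{-1}$ while defining
$D$ as the marginal standard deviations of $\Sigma$ itself; that form is
dimensionally inconsistent with its own definition, so the package uses
$D\,\Omega\,D$, which matches the stated meaning of $D$.

### Priors and identification

Weakly informative priors are used throughout: intercept
$c \sim N(0, 5)$ (5 read as a variance); two-way interactions
$N(0, 0.2^2)$; main-effect profiles $N(0, \sigma_A^2)$ with
$\sigma_A \sim t^+(\nu = 2.5, \text{scale} = 0.5)$, the same half-$t$ used
for the overdispersion sd; drift $\phi_1 \sim N(0, 2^2)$; autoregression
$\phi_2 \sim N(0.5, 0.2^2)$ truncated to $[0, 1]$; innovation sds
half-standard-normal.  The half-$t$ with 2.5 degrees of freedom is unusual
but adopted as stated by its source.  The break-indicator term and the
spread of the symmetric origin–destination prior have no stated priors; we
give the indicator a hierarchical main-effect prior (definition changes can
be large) and the spread the standard half-$t(2.5, 0.5)$.

Identification is handled softly through the hierarchy except for two hard
constraints, which hold exactly in every posterior draw: each $\kappa$
series is pinned to zero at the first observed period, and each bilinear
loading vector of length $L$ has free elements
$\mathrm{MVN}(\iota/L,\; L^{-2}\Psi^{-1})$ ($\Psi$ = 2 on the diagonal, 1
off it) with the last element set to one minus their sum, so loadings sum
to exactly one.

## Inference

Conditional on the per-cell latent $\log\mu$, the model is Gaussian in
every linear effect, in each bilinear loading vector (a small multivariate
normal solve), and in each $\kappa$ path (a banded Gaussian Markov field
combining the time-series prior with the loading-weighted likelihood).  The
sampler therefore uses exact Gibbs draws for all of these, vectorised
Metropolis with curvature-matched proposal scales
($\mathrm{sd} \propto (Y + \sigma^{-2})^{-1/2}$) for the latents, and
univariate slice sampling for scale and correlation parameters.  Two
further choices matter for mixing:

* *recentring moves*: the likelihood is invariant when a level mean of one
  term is shifted into a coarser term covering the same cells (an
  interaction's age means into the age main effect, any term's global mean
  into the intercept).  These null directions are sampled from their exact
  Gaussian conditionals, which removes the slow random-walk behaviour that
  softly identified log-linear models otherwise exhibit;
* *inner cycling*: each sweep iterates the loading/$\kappa$/dynamics blocks
  three times, since these blocks are mutually correlated along the
  bilinear ridge.

The latent $\log\mu$ is kept as a per-cell parameter (the augmented form)
rather than marginalised, preserving the overdispersion model exactly.
Initialisation is deterministic: effects and $\kappa$ at zero, scales at
their prior medians, latents at the empirical log rates.  Split-$\hat R$
and a basic effective-sample-size estimate are reported per parameter, with
a warning recorded (not an error) when $\hat R > 1.01$.  Some
level-vs-bilinear directions (for example a regional loading against the
break indicator) still mix slowly at small draw counts; the quantities that
drive forecasts — $\kappa$ paths, loadings, $\sigma$, predictors — are well
identified and recover their generative values in the test suite.

## Forecasting and projection

Per posterior draw, $\kappa$ paths are simulated forward from their fitted
dynamics, $\mathcal{M}$ is rebuilt for future cells with all other
parameters held at their posterior values, lognormal noise
$N(0, \sigma^2)$ is added and the result exponentiated.  Poisson count
variability is deliberately *not* simulated at forecast time: predictive
uncertainty reflects uncertainty about rates, the standard convention in
demographic forecasting.  The baseline population is treated as known.

The projection engine implements the classical multiregional
cohort-component arithmetic on five-year intervals: conditional
survivorship proportion matrices $\bar S_x$ (rows = origin, row sums 1) are
averaged to exact-age transition matrices
$\bar P_x = \tfrac12(\bar S_x + \bar S_{x-5})$, with
$\bar P_0 = \tfrac12(\bar S_0^2 + \bar S_0)$ for the youngest group and
$\bar P_z = \bar S_z$ for the open-ended group; a diagonal adjustment
$P^{DE}$ un-conditions them for mortality and emigration (requiring
$\tfrac52(d + e) < 1$, violations raise rather than clip); survivorship
matrices $S_x = (I + P_{x+5})\,P_x\,(I + P_x)^{-1}$ advance each cohort,
with $P_{z+5} := P_z$ closing the open-ended group; and newborns are
survived with $S_{-5} = [I + (I+P_0)^{-1}(I-P_0)]^{-1}$.  Because matrices
are stored row-origin, population column vectors advance as
$S^\top K$ — a dedicated asymmetric two-region test pins this orientation.
Births use annual fertility rates in diagonal matrices with the standard
$5/2$ factor, are split male:female 105:100 before sex-specific infant
survival, and the open-ended group accumulates survivors of the two oldest
cohorts.  Half of each interval's immigrants arrive before survival, half
after.

Annual component forecasts feed each five-year interval as the mean of its
five annual rates (immigrant counts are summed); internal migration is
forecast natively on the quinquennial grid.  Terminal-age migration
probabilities are mapped to cohort matrices by start age (the matrix for
the cohort starting in group $a$ comes from terminal group $a+1$; the
open-ended group reuses the terminal open-ended matrix).  The exact timing
of the lagged migration exposure (start-of-period population at age
$x - 5$) follows the standard transition-data convention; migrants recorded
in the first age group take the start-of-period population of that group.
Draws whose rates violate the un-conditioning precondition or whose
out-migration probabilities sum past one are excluded with a recorded
count rather than silently altered.

## Summary measures

Life expectancy at birth uses an abridged period life table consistent with
the engine's linear person-years assumption: $q_x = 5d/(1 + 2.5d)$,
$L_x = 5(l_x + l_{x+5})/2$, open-ended closure $L_z = l_z/d_z$.  No
published convention is attached to the reference forecasts, so this single
convention is used everywhere; conventions differing in $a_0$ or closure
shift $e_0$ by a few tenths of a year.  TFR is five times the sum of annual
age-specific rates over the reproductive window.  All quantile summaries
use linear-interpolation (type 7) quantiles, making interval endpoints
deterministic across platforms; intervals are nested by construction.

## The synthetic-data generator

`make_full_fixture()` builds a complete five-component system shaped like a
state-level national application: 8 regions with heterogeneous sizes (7.2m
down to 0.24m), 18 age groups 0–4…85+, annual vital series 1981–2011,
quinquennial migration observed 1986–2011 (six points), and an
international-migration definition break at 2004.  Truths are drawn from
the model's own priors where those are fixed-scale, with these deliberate
calibrations, chosen once for demographic realism:

* age *profiles* are plausible schedules plus noise — Gompertz-type
  mortality (slope 0.085 per year of age above 10, infant bump), a
  log-quadratic fertility hump centred near 27, a bounded young-adult bump
  for migration-type components — because fully random age profiles produce
  nonsensical summary measures (e.g. life expectancies of centuries);
* overall levels: migration probabilities around 0.01 per flow, mortality
  and fertility levels implied by their schedules, immigration around 1500
  per cell, emigration around 0.004;
* dynamics: AR coefficients 0.6, annual innovation sds 0.08 (0.15 for the
  quinquennial migration series), mortality drift about $-0.25$ per year on
  the $\kappa$ scale ($\approx$ 1.4%/year average rate decline), strongly
  correlated male–female innovations ($\rho = 0.8$), overdispersion
  $\sigma = 0.08$;
* hierarchical scales are set to fixed plausible values rather than drawn
  from their heavy-tailed half-$t$ priors, so fixtures are stable across
  seeds;
* the generator verifies that the implied system stays inside the
  projection model's domain ($\tfrac52(d+e) < 1$, out-migration row sums
  below one) over the observed span *and* a drift-extended three-interval
  horizon, scaling a component's overall level down if its stylised tails
  breach the cap.  Real systems sit far inside these bounds; the guard only
  trims the generator's tails.

The generator emulates the *structure* of register/census demographic data,
not its pathologies: no measurement error, no census undercount, no
harmonisation breaks beyond the single definition change, and exposures are
internally consistent by construction.  Passing recovery tests therefore
demonstrates correctness of the inference machinery under a well-specified
model, not robustness to real-data misspecification.

## Model selection harness

Following the reference workflow, candidate structures are compared in
simplified form: bilinear terms dropped, the remaining log-linear model fit
by maximum likelihood as a Poisson GLM with log-exposure offset.  RMSE is
computed on log-rate residuals over positive-count cells (zero counts have
no finite log rate; this restriction is the package's documented choice,
matching the lognormal model scale), and BIC as
$-2\log L + p\log(\text{cells})$.

## Problem sizes and reproducibility

The test suite fits 3-region systems (seconds per fit) for bookkeeping and
constraint checks, and the full default-shape 8-region fixture at 2 chains
× 250 retained draws for parameter recovery; the acceptance script refits
all five components on the default fixture at 2 × 200 draws, forecasts
three five-year periods and projects all retained draws, completing in a
few minutes on one CPU.  These sizes are the package's reference
configuration for its own verification; larger runs scale linearly in
cells × sweeps.  All randomness flows from explicit seeds: per-chain seeds
in `fit_component()`, named per-component offsets in the staged pipeline,
and a single `--seed` in the acceptance script.  Identical seeds reproduce
draws, forecasts and projections bit-for-bit.

## Known limitations

* Single-draw-at-a-time forecasting keeps memory flat but makes the
  forecast stage the slowest part of large runs.
* The sampler reports, but does not remedy, slow mixing of a few softly
  identified level contrasts at very small draw counts.
* Male and female life expectancies are forecast without a coherence
  constraint and may diverge over long horizons.
* The open-ended age group is not graduated; all within-group heterogeneity
  above 85 is collapsed.
* Baseline-population uncertainty and count-level (Poisson) forecast
  variability are out of scope by design.
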