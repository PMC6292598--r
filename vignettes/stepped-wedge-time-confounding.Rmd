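---
title: "Calendar and exposure time in stepped wedge trials: models, simulation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calendar and exposure time in stepped wedge trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swcrtmix)
```

## The problem

In a stepped wedge cluster randomised trial (SWCRT), clusters cross from
control to intervention at randomised, staggered time steps and never
revert. The consequence is that treated and untreated observations are not
contemporaneous: late calendar time is mostly intervention time. Any
secular trend in the outcome — drift in case mix, seasonality, service
changes — is therefore partially confounded with the intervention effect.
A second clock matters too: *exposure time*, the time since a given
cluster's own crossover, along which cumulative intervention effects
develop. An analysis model must say something about both clocks, and what
it says determines whether the intervention effect is estimated reliably.

`swcrtmix` provides the machinery to study this question by simulation for
the closed-cohort SWCRT (the same participants measured at every step): a
design layer, a scenario-driven data generator, a maximum-likelihood
mixed-model engine, nine candidate fixed-effect formulations of time with
contrast-based effect estimation, and a replicate grid that scores each
formulation by coverage probability, bias, confidence interval width, mean
squared error and BIC. A re-analysis mode applies the full nine-model
comparison to a real trial dataset.

## Design and notation

`standard_design(K, m)` builds the standard layout: `n = K + 1` calendar
steps, all clusters under control at step 1, one cluster crossing over at
each subsequent step, `m` participants per cluster present throughout.
Calendar time at step `t` equals `t`. The treatment indicator is
`x[t, k] = 1` iff `t >= s_k`, where `s_k` is cluster `k`'s crossover step,
and exposure time is `d[t, k] = max(t - s_k + 1, 0)`, so the first treated
step has `d = 1` and the maximum attainable exposure is `n - 1`. The
default schedule assigns cluster `k` to step `k + 1`; randomising the
rollout order is available via a seed but does not affect any simulation
summary, because clusters are exchangeable in the generating model.

```{r}
d <- standard_design(3, 1)
treatment_matrix(d)
```

## The generating model

`simulate_trial()` draws, for scenario mean `mu(t, d, x)`,

* a cluster intercept `gamma_k ~ N(0, sigma_gamma^2)`,
* a participant intercept `h_i ~ N(0, sigma_h^2)`,
* a residual series per participant from the stationary AR(1) recursion
  `eps_t = rho * eps_{t-1} + s_t`, with `eps_1 ~ N(0, sigma^2)` and
  innovations `s_t ~ N(0, (1 - rho^2) * sigma^2)`,

and returns `y = mu + gamma_k + h_i + eps`. The rescaled innovation
variance is what makes the residual process stationary: the marginal
variance is `sigma^2` at every step and the lag-`r` within-participant
correlation is `rho^r`. Both properties are verified by Monte Carlo in the
test suite.

The default variance components are `sigma_gamma = 0.96`,
`sigma_h = 4.42`, `sigma = 5.44` (HoNOS score units, the 0–48 mental
health outcome scale for which the scenario library was built), with
`rho = -0.5` for odd-numbered scenarios and `+0.5` for even-numbered
ones. A negative lag-1 residual correlation is unusual for repeated
measures but is retained deliberately: it is what the motivating trial
data estimated, and it turns out to matter for coverage (see below). All
components are overridable through `variance_components()`.

The 36 scenarios of `scenario_table()` share intercept 14 and combine a
step effect (`delta` = 0, +2 or −2), linear calendar and exposure slopes
(`tau` = 0.25, `psi` in {0.15, 0.25, −0.50}), and sinusoidal profiles:
half-cycle and full-cycle calendar trends `K1`/`K2` of amplitude 2, and
exposure trends `X1`/`X2` of amplitude 1 that are zero at `d = 0` and
`d = 1` (the profile argument is `d - 1`, so the cumulative effect starts
one step after crossover). Linear terms and profiles never co-occur in a
scenario.

## The estimation engine

All nine formulations are linear mixed models with the same random part —
nested cluster and participant intercepts — and a within-participant
residual covariance that is either independent (`"CS"`, which together
with the participant intercept induces compound symmetry of the response)
or AR(1) (`sigma^2 * rho^|t_a - t_b|`). Estimation is full maximum
likelihood, so BIC comparisons across mean models are valid.

Numerically, `fit_ml()` profiles the fixed effects out by generalised
least squares and the residual variance out in closed form, leaving a 2-
(CS) or 3-parameter (AR1) optimisation over log variance ratios and
`atanh(rho)`. The unconstrained transforms avoid boundary constraints;
near-zero cluster variances, common with 12 clusters, are reported rather
than errored. Nelder–Mead with relative tolerance `1e-10` (well inside the
`1e-8` convergence contract) is used, with a second dispersed start on
non-convergence; fits are deterministic given data and start.

The likelihood itself is evaluated blockwise with an exact two-level
Woodbury factorisation: the within-participant matrix
`A = C(rho) + sigma_h^2/sigma^2 * J` (at most `n x n`) is inverted
directly, and the cluster intercept enters each cluster's precision as a
rank-one correction. This is algebraically identical to factorising each
cluster's full `(m*n) x (m*n)` covariance — the test suite checks
agreement with a dense full-covariance log-density to `1e-8` on random
instances — but costs milliseconds instead of the dense factorisation's
~`(mn)^3/3` flops per likelihood evaluation, which is what makes
replicate grids at 200–1000 replicates per cell practical on a single
core. Balanced datasets additionally share one `A` inverse across all
participants. The engine's fixed effects, log-likelihoods and AR(1)
correlation estimates are cross-checked against `nlme::lme` (ML) in the
tests; agreement is ~`1e-6` on the log-likelihood.

## Formulations, estimands and truth

The nine formulations (`M1`..`M9`, see `formulations()`) span: no time
(`M1`); continuous calendar time without (`M2`) and with (`M3`) an
intervention interaction; continuous calendar plus exposure time with
(`M4`), without (`M5`) a step term, and with an added quadratic (`M6`);
categorical calendar time (`M7`, the Hussey–Hughes model); categorical
calendar time with a categorical intervention interaction (`M8`); and
categorical calendar plus categorical exposure time (`M9`).

Two identifiability constraints deserve note, both enforced by
`design_matrix()` with reference-cell coding (`kappa_1 = 0`,
`xi_0 = 0`):

* **M8**: in a SWCRT the interaction of treatment with categorical time is
  only partially identifiable. At `t = 1` no cluster is treated, at
  `t = 2` the single treated cluster's effect is absorbed by the step
  term, and at `t = n` all clusters are treated, so there are no control
  observations against which an interaction could be estimated — `kappa_n`
  then measures the calendar effect *under* the intervention. Interaction
  columns therefore exist only for `t = 3..n-1` (ten columns in the
  standard 12-cluster design). Requesting the unrestricted interaction
  raises a rank error naming the aliased columns.
* **M9**: an explicit intervention column is redundant because treatment
  (`x = 1`) is exactly `d >= 1`, i.e. nested within categorical exposure;
  adding it raises the same rank error.

Both intervention-effect estimands are linear contrasts (`contrast()`)
with Wald inference (`estimate_effect()`, normal reference by default, a
`t` reference with residual degrees of freedom as an option): the effect
at six steps of exposure, and a time-averaged effect. For the interaction
formulations the "six month" reading is the effect at calendar time 6
(`delta + 6*omega` for M3, `delta + phi_6` for M8) and the time average is
taken at the median calendar time (7 of 13) or over `phi_3..phi_12`; for
exposure formulations it is `delta + 6*psi` (or `6*psi`, `xi_6`), and the
time average for linear exposure coincides with the six-month value
because `d = 6` is the median of the exposure range.

`true_effect()` applies the same definitions to the generating model, so
the truth used for coverage depends only on the scenario — e.g. 2 for the
pure step scenario D9, `2 + 6*0.25 = 3.5` for D17, and
`2 + sin(5*pi/12) = 2.97` for the sinusoidal D27.

## The replicate grid and its metrics

`run_cell()` simulates, fits and scores one (scenario, formulation,
structure) cell; `run_grid()` crosses them from a flat YAML config. Two
shipped configs document the intended operating points:
`inst/extdata/paper_full.cfg` (all 36 scenarios x 9 formulations x 2
structures at 1000 replicates — a long batch run) and
`inst/extdata/desk.cfg` (a 4-scenario, 4-formulation CS subset at 200
replicates, the size used throughout the package's own tests; at 200
replicates the binomial Monte Carlo band around a true coverage of 0.95
is roughly ±0.03).

Seeding is two-level: a master seed plus a fixed integer hash of
(scenario, replicate) gives each replicate an independent substream. Every
cell of a grid therefore analyses the *same* simulated datasets (as when a
set of candidate models is fitted to each simulated trial), any cell can
be recomputed in isolation, and reruns are bit-identical.

Metric conventions, where the underlying definitions admit choices:

* **Coverage** is the proportion of converged replicates whose 95% CI
  contains the scenario truth; non-converged replicates are dropped from
  all metric denominators but counted (`n_converged`), and a
  `coverage_all_reps` column reports the all-replicates denominator as a
  sensitivity.
* **MSE** uses conditional fitted values — fixed effects plus BLUPs of
  both random intercepts — as the default, matching what standard
  mixed-model software reports; a marginal (fixed-effects-only) option is
  retained, and the tests verify the conditional MSE is the smaller.
* **BIC** counts fixed effects plus variance parameters (3 under CS, 4
  under AR1). Any consistent convention preserves cross-model rankings at
  a fixed random structure; this one matches the ML parameter count.

## What the simulations show, and their limits

The package's own acceptance tests reproduce the directional core of the
methodology: under scenarios with genuine exposure-time effects (D17,
D27), the Hussey–Hughes formulation's six-month coverage collapses (0.02
and 0.50 at 200 replicates), while the categorical time + exposure model
M9 stays near nominal everywhere. Simpler formulations buy narrower
intervals (M1's CI is roughly half of M9's width) at the price of
catastrophic under-coverage when their time model is wrong.

One nuance the simulations expose: fitting the CS structure to data whose
residuals are AR(1) with *negative* lag-1 correlation is conservative —
M9/CS coverage on the `rho = -0.5` scenarios sits at 0.98–0.99 rather
than 0.95, while the correctly specified AR(1) fit of the same replicates
achieves ~0.96. The fixed-effect estimates themselves are essentially
unchanged between CS and AR(1) fits; misspecifying the covariance moves
interval calibration slightly, misspecifying the mean's time structure
moves the estimates a lot.

The generator emulates a closed cohort with Gaussian outcomes, exchange-
able clusters and no missingness. Real trial data — including the kind of
deposited dataset the re-analysis mode targets — have unbalanced cluster
sizes, dropout, integer-valued bounded outcomes and possibly
time-varying cluster composition, none of which the passing tests speak
to. The engine itself accepts unbalanced groupings and irregular
observation times (AR(1) correlation decays with the actual time gap),
so the re-analysis path does not depend on balance.

## Degenerate inputs and numerical edges

* Variance components at the boundary (`sigma_gamma -> 0`) are reachable
  on the log scale and reported as near-zero estimates, not errors.
* `|rho| >= 1`, negative SDs, rank-deficient design matrices and
  inconsistent `(treated, exposure)` pairs raise immediate argument
  errors; CSV readers validate schema, duplicates and the
  exposure-advances-by-one rule before any model sees the data.
* A non-positive-definite within-subject block (impossible for admissible
  parameters but reachable through user-supplied extreme `rho` with
  irregular times) is caught at the Cholesky and reported as a
  parameter-domain error; the optimiser treats such points as infinitely
  penalised rather than failing.
* All-replicate non-convergence in a cell yields a flagged invalid
  summary with a warning, never a silently empty row.

## Reproducing the reference quantities

`scripts/acceptance.R --seed <int> --out <path>` recomputes the package's
deterministic reference values (the scenario library's trend-profile
values at their defining grid points) directly from the installed package
and writes them as JSON; the seed argument fixes the RNG for uniformity
even though these particular quantities are closed-form. The full
simulation comparison is run through `run_grid()` with the shipped
configs, as described above.
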