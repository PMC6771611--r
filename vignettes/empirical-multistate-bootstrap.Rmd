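---
title: "Hazard-based simulation and the IPD-free bootstrap for multistate data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hazard-based simulation and the IPD-free bootstrap for multistate data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsim)
```

## The model

A multistate process `X_t` on a finite state space is driven entirely by
its transition intensities
`α_lm(t) dt = P(X_{t+dt} = m | X_{t−} = l)`, with cumulatives
`A_lm(t)` and the diagonal convention that each row of the intensity
matrix sums to zero.  States without outgoing intensities are absorbing.
`emsim` assumes a time-inhomogeneous Markov process by default; the
`history` argument of `hazard_fn()` (current state, arrival time, visit
counts, full path) lets intensities depend on the past, e.g. on the
duration in the current state, in which case the Aalen–Johansen estimator
still targets the state-occupation probabilities under random censoring.

A trajectory is built as a nested sequence of competing-risks
experiments: draw the waiting time in the current state from the
all-cause survival `exp(−(A_l·(t) − A_l·(t*)))`, *then* draw the
destination with probabilities `α_lm(T)/α_l·(T)` at the realized time `T`.
Two consequences matter and are asserted by tests:

* nothing is ever conditioned on the future — the transition type is
  decided after the event time, so internal time-dependent covariates
  (modelled as transient states) evolve as part of the mechanism;
* no latent times exist — only real-world quantities such as the
  exposure-free survival (first exit from the initial state) and the
  overall survival (absorption time) are generated, and `EFS ≤ OS` holds
  path by path, with equality exactly for deaths without prior exposure.

## Time-dependent exposures

For one dichotomous internal exposure, the package uses the illness-death
formulation: state 0 unexposed-alive, 1 exposed-alive, 2 dead, with
`α_02 = α_0`, `α_12 = α_0 e^β` (a Cox structure) and an exposure hazard
`α_01`.  The population survival hazard is then the prevalence-weighted
mixture `α(t) = w_0(t) α_0(t) + w_1(t) α_0(t) e^β`
(`population_hazard()`), and the expected fraction exposed by `t` is the
cumulative incidence
`∫_0^t exp(−(A_01 + A_02)(u)) α_01(u) du`
(`cumulative_incidence_exposure()`), which under constant hazards is
`a_01/(a_01+a_02) (1 − e^{−(a_01+a_02)t})`.

The traditional latent-failure-time generator (draw a time-to-exposure
and two dummy survival times, then combine) is provided as
`simulate_latent()`, deliberately documented as an *oracle only*: it
lives on a sampling space impossible in real life (patients who can die
twice, exposure times for the dead), even though its marginal `(EFS, OS)`
law agrees with the multistate route — an equivalence the test suite
verifies by two-sample Kolmogorov–Smirnov tests at n = 100,000.  The
conditional-survival formula `P(T > t | T0 = t0)` is implemented with the
standard reading `exp(−A_0(t))` for `t ≤ t0` (the two-branch form is
continuous at `t0` and nonincreasing); only properties shared by both
possible readings of its first branch are asserted.

## The empirical hazard measure

`nelson_aalen()` turns long-format records into increments
`ΔÂ_lm(u) = #events / #at-risk` with the left-limit risk-set convention:
a subject entering exactly at `u` (delayed entry) is *not* at risk at
`u`; a subject whose record ends at `u` — by event or censoring — still
is.  All transitions tied at `u` share one joint product factor.  Times
with no events do not enter the grid.  The same table format
(`time, from, to, increment[, risk_set]`) is what one would digitize from
published cumulative-hazard plots, and `read_increments()` accepts the
cumulative form directly.

`simulate_empirical()` samples from that measure: the waiting time out of
state `l` entered at `t*` follows the Kaplan–Meier-type law
`F̂_l(t) = 1 − ∏_{t*<u≤t}(1 − ΔÂ_l·(u))`.  Probability mass not spent by
the largest observed event time is a residual atom; a subject drawing it
is **censored at that largest observed time** (the information-preserving
reading of "censor beyond the last time").  Destinations are drawn
proportional to the transition-specific increments at the realized time.
Event times therefore live on the source grid — when the number of
simulated subjects greatly exceeds the source sample size the output
distribution is visibly discrete; this is a property of the method, noted
rather than smoothed away.  An independent censoring law can be
superimposed; its draws may fall off-grid and simply clip the trajectory
(the package does not force superimposed censoring onto the grid, a
choice the source material leaves open).

Internally the sampler precomputes, per state, the cumulative
log-survival over the state's grid positions and inverts it by binary
search, so one uniform draw yields the next event position; this is what
makes the nested experiments below run in minutes on one CPU.

## Estimation and variances

`aalen_johansen()` evaluates `P̂(s,t) = ∏_{s<u≤t}(I + ΔÂ(u))` (exact
Chapman–Kolmogorov on grid-aligned splits; row sums 1 within 1e-10, the
tolerance used for all probability-sum checks).  `aalen_variance()` runs
the recursion for the covariance of `vec P̂(0,t)`:
with `F = I + ΔÂ(u)`,
`Σ(u) = (F' ⊗ I) Σ(u−) (F' ⊗ I)' + (I ⊗ P̂(0,u−)) Ψ(u) (I ⊗ P̂(0,u−))'`,
where `Ψ(u)` is the multinomial covariance of the increments,
`cov(ΔÂ_lm, ΔÂ_lm') = (δ_mm' ΔÂ_lm − ΔÂ_lm ΔÂ_lm')/Y_l(u)`, extended to
the diagonal entries by linearity.  In the one-event survival case this
reduces exactly to the one-term Greenwood value, and a 500-replication
two-state experiment confirms ~95% coverage of the log-log Wald interval
(`loglog_ci()`, bounds `p^{exp(∓ z √v /(p log p))}`, degenerate `p`
returning the point).

`censoring_km()` estimates the censoring distribution by reverse
Kaplan–Meier with events preceding censorings at ties (matching
`survival::survfit` on role-swapped data); residual mass means "never
censored".

## The bootstrap and the coverage experiments

`empirical_bootstrap()` draws `B` study-sized datasets from the estimated
increments, re-estimates each one fully (its own Nelson–Aalen, product
integral, and its own empirical initial proportions), and reports
percentile intervals using empirical quantiles with linear interpolation
(`quantile` type 7 — the convention had to be fixed, and this is R's
default).  The information set is deliberately IPD-free: an increment
table, an initial distribution and a censoring law.

`coverage_experiment()` nests this inside a simulation study: studies are
drawn from a constant-hazard truth model, and the fraction of studies
whose interval covers the matrix-exponential truth is reported with its
Monte-Carlo standard error `√(c(1−c)/R)`.  Two design choices deserve
explanation:

* **Replicate initial states come from the design's published initial
  proportions** (0.43/0.57 in the liver-cirrhosis scenario), not from
  each study's empirical proportions.  This is the information a
  published-data user actually has, and it reproduces the characteristic
  mild over-coverage of the initial-state occupation probability (≈97%
  at every sample size): the interval width carries the initial-state
  binomial variability while its centre does not inherit the study's
  initial-state sampling error.  With study-wise proportions instead,
  all cells sit at the nominal ~95%.
* **Replicate censoring re-applies the generative Uniform(0, 4400)
  law.**  The alternative — estimating the censoring law per study by
  reverse Kaplan–Meier — is available via `censoring_km()` and is the
  natural choice when the generative law is unknown.

Cells whose truth is exactly 0 or 1 are flagged `degenerate` and should
be read separately (the estimator typically equals the truth there).
Fewer than 50 studies are refused outright.

## What the generator emulates — and what it does not

The `"csl-constant"` preset encodes the liver-cirrhosis scenario: an
illness-death model with recovery, constant daily transition rates
0.0005 / 0.0002 / 0.002 / 0.0012 (the transition-specific incidence rates
of the motivating trial), initial proportions 0.43/0.57, Uniform(0, 4400)
censoring, time in days.  Constant hazards make the truth analytic
(`π e^{tQ}`), which is what the coverage experiments need.  Real registry
data have time-varying intensities, covariate heterogeneity and dependent
censoring, none of which the preset emulates — passing the coverage
checks shows the bootstrap is calibrated *for this class of generator*,
not that it is calibrated for any particular real dataset.  The
late-time cells (t ≥ 2700 days) show genuine undercoverage for the
nearly-extinct transient state at small n; this known failure mode is
asserted, not patched.

## Problem sizes and numerical choices

The shipped experiments use 300 studies × 300 bootstrap replicates for
n = 50/100/251 and 200 × 200 for n = 500 — large enough for ~1.3-point
Monte-Carlo standard errors on a coverage while keeping the whole suite
within a couple of minutes.  The fixed-point check re-simulates 200,000
subjects from a 5,000-subject source with administrative censoring at
day 1500: the administrative horizon keeps every risk set above ~25% of
the cohort, so the per-atom binomial noise (~1e-4) sits far below the
4/√m Monte-Carlo bound being asserted; with heavy random censoring the
late-time risk sets would be nearly empty and the per-atom bound would be
unattainable for any implementation.  Other numerics: waiting-time
inversion for non-constant hazards uses bracketed root-finding with
tolerance 1e-10 on adaptive-quadrature cumulatives; the analytic truth
uses an eigendecomposition fast path (fallback `Matrix::expm`, and a
fine-grid product integral for non-constant models); probability-sum
assertions use 1e-10 throughout.

All randomness flows through R's RNG, including the C++ kernels, so any
result is a deterministic function of (inputs, configuration, seed); the
package runs single-threaded, and determinism is asserted at that level
rather than per-subject substreams.

## Limitations

* Continuous covariate processes are out of scope: covariates enter only
  as (finitely many) transient states.
* No smoothing or parametric preprocessing of increment tables is
  offered; the discreteness of empirical event times is inherited by
  design.
* Cox regression fitting, landmark estimators for non-Markov transition
  probabilities, and additive-hazard model fitting are not implemented
  (the history hook exists, the fitting does not).
* State-dependent censoring is expressible only by adding explicit
  censoring states to the model configuration.
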