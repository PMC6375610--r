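---
title: "Methods: cohort demography, thermal response, survival and fecundity models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort demography, thermal response, survival and fecundity models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestdemog)
```

pestdemog analyses cohort experiments on stored-product insects reared at
constant temperatures: individuals followed daily from oviposition through
egg, larval and pupal stages to adult death, with daily egg counts for
females. This vignette documents the models, the tunable parameters, the
numerical choices, and the limits of what the test suite establishes.

## The synthetic-data generator

No raw data ship with the package; a seeded generator
(`generate_cohort()`) produces cohorts with the statistical structure the
analysis assumes.

**Generative model.** Time is discrete in whole days (the emulated
experiments record every 24 h). Each individual draws stage durations as
shifted Poisson variables, `1 + Poisson(mean − 1)`, so every stage lasts
at least a day; the distribution is not identified by daily records of
this kind, and the shifted Poisson is the simplest single-parameter
integer-support choice. Stage survival is Bernoulli per stage; an
individual dying in a stage dies on a uniformly chosen day of that stage.
Adults draw a lifespan from a configurable distribution (lognormal by
default — adult lifespans in these experiments are right-skewed). Sex is
Bernoulli(0.5) by default: the emulated study sexed offspring but
reported no ratio, so the uninformative 1:1 default is an assumption.
Females begin laying after a geometric preoviposition delay
(`1 + Geometric`, mean as configured); the geometric tail produces the
right-skewed time-to-first-egg that makes lognormal-type AFT models win,
matching the published model selection. Each day of the laying window
yields a zero-inflated Poisson count: zero with probability `p`,
otherwise Poisson(`λ`). The recorded fecundity series starts at the end
of the preoviposition delay, so the zero fraction of the recorded
female-days is exactly `p + (1−p)e^{−λ}` in expectation — the property
the tests check.

**RNG.** One Mersenne–Twister stream per cohort, seeded from
`config$seed`, with all draws vectorised in a fixed order. Identical
seeds give byte-identical cohorts. (A per-individual sub-stream design
was considered and rejected: it forces a per-individual loop for no
testable benefit, since record-level determinism is what the contract
demands.)

**Presets.** `default_scenario()` encodes three temperature presets whose
*orderings* — not values — mirror the emulated biology: development
accelerates and adult life shortens from 30 to 40 °C; the net
reproductive rate is far above one at 30/35 °C and below one at 40 °C;
the zero fraction of daily egg counts exceeds 0.90 everywhere; at 40 °C
most females die before laying, which is what makes the first-egg
endpoint heavily censored. Cohort sizes default to the egg numbers of the
emulated design (40, 48, 433): the hot treatment needs a large cohort
because pre-adult mortality near the upper thermal limit would otherwise
frequently leave no reproducing female at all, making the intrinsic rate
undefined. Egg production at these presets is clustered (high `p`, high
`λ`: rare days with large clutches) so that the > 0.90 zero fraction and
a realistic lifetime fecundity coexist; khapra-type beetles do lay in
bouts, but the specific preset values are calibration conveniences, not
measurements. No attempt is made to reproduce the published parameter
*values*, which depend on unpublished raw cohorts.

## Life table and demographic parameters

`build_life_table()` counts both sexes in `lx` (proportion with death age
> x; `l0 = 1` because ages are counted from oviposition and every death
age is ≥ 1). `mx` is the mean egg count at age x per female *alive* at x,
times the female ratio. The emulated study does not state its `mx`
denominator; alive-at-x is the standard cohort construction and the
default, with `mx_denominator = "initial"` exposed for the alternative.
Because age 0 is oviposition, generation time includes development — which
is why published generation times (~69 d at 30 °C) far exceed adult
lifespan alone.

The intrinsic rate solves `Σ e^{−r x} lx mx = 1`. The equation is often
printed without the minus sign in applied papers; only the standard form
is consistent with positive `r` when `R0 > 1` and the negative rates
reported near the upper thermal limit, so that is what is implemented.
The left side is strictly decreasing in `r`, so the root is unique; it is
bracketed in `[−10, 10]` d⁻¹ (extended automatically), solved by Brent's
method and polished with Newton steps to |residual| < 1e−12. Tests
compare against an independent bisection oracle to 1e−8 and verify the
`V0 = 1` identity of the reproductive-value schedule, which holds by
construction exactly when `r` is the Euler–Lotka root. Degenerate inputs
are errors, not sentinels: no reproduction (`R0 = 0`) and `r = 0` (for
`T` and `DT`) raise informative conditions.

A caution inherited from practice: published tables of bootstrap *means*
of `(R0, r, T, DT)` are not mutually consistent through the closed forms
(`T = ln R0 / r` etc.). The package never "corrects" user-supplied
values; it only derives parameters from data.

## Bootstrap

The resampling unit is the whole individual (life history), preserving
the dependence between survival and fecundity within an insect. Each of
`B` (default 1000) replicates resamples n individuals with replacement
and recomputes all five parameters. Intervals are empirical 2.5%/97.5%
quantiles with linear interpolation (R type 7 — documented because the
percentile definition changes the third decimal on small B). Replicates
where a parameter is undefined (no reproduction in the resample) are
counted in `n_failed` and excluded from that parameter's percentiles;
silently dropping them would hide exactly the cohorts where collapse is
likely, so the count is reported. `wald_compare()` implements the
z-statistic on two estimates with supplied standard errors and also
reports 95%-CI overlap, the informal superposition check.

## Brière thermal model

`r(T) = a·T·(T − T0)·√(TL − T)`. Fitting profiles `a` out analytically
(it enters linearly) and searches `(T0, TL)` by a deterministic grid plus
`nlminb` refinement — multi-start because the surface can be multimodal.
Constraints: `TL ≥ max(T)` (the model is undefined above `TL`; with a
negative observed rate at the hottest treatment the optimum sits on this
boundary, reproducing the published `TL = 40.00`), and
`T0 ∈ [0, min(T)]`.

One subtle choice: inside the least-squares objective the basis is the
*signed* analytic expression for all `T ≤ TL`, not clamped to zero below
`T0`. With a clamped objective, an assumed-zero cold anchor below `T0`
has zero residual no matter where `T0` sits, so the anchor stops
informing the fit and `T0` drifts upward (to ≈ 21.8 °C on the published
four-point summary). The signed basis penalises overshooting the anchor
and keeps `T0` near it (17.2 °C, R² ≈ 0.70), consistent with the
published estimates. User-facing predictions (`briere_r()`) clamp to zero
outside `[T0, TL]`, the biologically meaningful convention. `R²` uses
`SS_tot` about the mean observed rate; for exactly flat data
(`SS_tot = 0`) it is defined as 1 when the fit is exact and 0 otherwise —
arbitrary but testable. The optimum is the larger root of
`5T² − (3T0 + 4TL)T + 2T0TL = 0`, verified numerically against an
argmax.

Exact reproduction of published `(a, T0, TL)` is not guaranteed: whether
such fits used rounded two-decimal rates or unrounded estimates is
unknowable from printed tables, so the acceptance check brackets `R²` in
[0.67, 0.71] and `T0` in [17.0, 19.9].

## Survival models

`km_fit()` implements the product-limit estimator with Greenwood
variance. Confidence bands use the log transform,
`exp(log Ŝ ± 1.96·se(log Ŝ))` truncated to [0, 1] (the band construction
is rarely stated in applied papers; the log transform is `survfit`'s
default and the tests pin agreement with it to 1e−10). The "mean" under
censoring is the restricted mean up to the largest observed time,
disclosed as such — an unrestricted mean is uninterpretable when the
heaviest-censored group never crosses 0.5. The median is the smallest
event time with `Ŝ ≤ 0.5` (so a flat stretch at exactly 0.5 reports its
left endpoint), with CI from the times where each band first drops to
0.5; all three are `NA` when never reached.

Endpoints are derived from the event history: time to death (every
individual, never censored — by design the experiments observe all
deaths) and time to first egg (females only; a female dying before her
first egg is censored at her death age).

AFT fits use `survival::survreg` behind the package's contract:
temperature enters as a single continuous covariate — the published
parameter counts (2 for exponential, 3 otherwise) are only consistent
with one slope, not a three-level factor. `AIC = −2ℓ + 2k` exactly;
selection takes the minimum, ties break toward fewer parameters, then
input order. Fits carry a sample fingerprint so rankings across different
samples are refused.

## Zero-inflated Poisson posterior

The daily count model: `y = 0` with probability `p`, else
`y ~ Poisson(λ)`, pooled over female-days per temperature group (the
emulated analysis has no per-individual random effects). Priors:
`p ~ Uniform(0,1)`, `log λ ~ Normal(0, 10²)` ("mean zero, large
variance"; the sd is exposed).

The sampler is data-augmentation Gibbs. Each zero observation has a
latent indicator (structural vs Poisson zero) with conditional
probability `p / (p + (1−p)e^{−λ})`; given the indicators, `p` has a
conjugate Beta update, and `log λ` takes an adaptive random-walk
Metropolis step (batch adaptation toward 0.44 acceptance during burn-in,
frozen afterwards so the kept chain is Markov). Defaults are 7000
iterations with 4000 burn-in, matching common practice for this model
size; split-chain R̂ on the recovery example is < 1.01. The primary
correctness oracle is a brute-force posterior by 2-D grid quadrature over
`(p, log λ)` on small instances — the sampler must match its means within
Monte-Carlo error. Degenerate inputs: all-zero data yield a warning, not
an error (the data then pin only the marginal zero probability near 1 —
`p` large and `λ` tiny are indistinguishable); empty input recovers the
priors exactly, which the tests use as a further sampler diagnostic.

"Probability of excess zeros" is reported as the marginal
`p + (1−p)e^{−λ}` per posterior draw: published values of that quantity
(~0.80 at moderate temperatures) are consistent with this formula applied
to posterior means, not with `p` alone. Note the emulated study reports
*observed* zero fractions above 0.90 alongside model zero-probabilities
near 0.80 — a discrepancy (plausibly differing observation windows) that
the package does not attempt to resolve; the generator's presets simply
make both exceed 0.90. Group comparisons report a Wald z on posterior
means with posterior sds as standard errors (the loose "Bayesian
p-value" construction) *and* the direct `Pr(λ_a > λ_b)` from paired
draws, which is the cleaner Bayesian statement.

## Interpretation: what a green suite establishes

The tests establish (i) exact agreement with hand-computable cases and
published desk-scale arithmetic; (ii) agreement of every nontrivial
estimator with an independent oracle (bisection, `survfit`, closed-form
MLEs, grid quadrature); (iii) distributional properties of the generator
and statistical calibration (coverage, type-I error, parameter recovery)
at Monte-Carlo tolerances with fixed seeds. They do not establish that
the presets reproduce any particular laboratory population — synthetic
cohorts lack between-individual heterogeneity in fecundity rate,
temperature-dependent egg viability, and diapause, all of which occur in
real stored-product beetles. Conclusions about real cohorts require real
event histories via `read_event_history()`.

## Known limitations

- Fecundity days are pooled across females in the ZIP model; overdispersed
  individuals would need a random-effects or ZINB extension (deliberately
  out of scope).
- No Leslie-matrix projection or stable-age distribution; no Cox model or
  log-rank test; no interval censoring despite daily inspection
  granularity.
- The bootstrap is plain percentile (no BCa); at small n its coverage is
  approximate, which the acceptance test bounds only up to Monte-Carlo
  error.
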