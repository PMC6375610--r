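# pestdemog

Deterministic and stochastic demography of stored-product insect cohorts,
built around the life history of heat-adapted pests such as the khapra
beetle reared at constant temperatures (30/35/40 °C). The package is aimed
at quantitative entomologists and biostatisticians who follow cohorts from
oviposition to death, recording stage transitions daily and female
fecundity per day, and who want both the classical deterministic summary of
such an experiment and stochastic models of its components.

## What it computes

**Cohort life table and demographic parameters.** From individual event
histories: survivorship `lx`, age-specific mortality
`qx = 1 − l(x+1)/l(x)` and fecundity `mx` (eggs × sex ratio), then

- net reproductive rate `R0 = Σ lx·mx`,
- intrinsic rate of increase `r`, the unique root of the Euler–Lotka
  equation `Σ e^(−r·x) lx·mx = 1` (solved to |residual| < 1e−12),
- finite rate `λ = e^r`, mean generation time `T = ln(R0)/r`, doubling
  time `DT = ln(2)/r` (negative when the population collapses),
- reproductive value `Vx` and life expectancy `Ex` schedules.

Uncertainty comes from bootstrap resampling of whole individuals (default
B = 1000) with empirical 2.5%/97.5% percentile intervals, plus a Wald
z-comparison between groups.

**Thermal performance.** The Brière model
`r(T) = a·T·(T − T0)·√(TL − T)` is fitted to (temperature, intrinsic-rate)
points by profiled least squares, with a closed-form optimum temperature
(the larger root of `5T² − (3T0 + 4TL)T + 2·T0·TL = 0`).

**Survival analysis.** Kaplan–Meier product-limit curves with Greenwood
variance and log-transformed bands for time to death (uncensored by
design) and time to first egg (right-censored when a female dies childless
— at 40 °C the curve never crosses 0.5 and the median is undefined), plus
accelerated-failure-time fits (exponential, Weibull, lognormal,
loglogistic; temperature as the covariate) ranked by
`AIC = −2ℓ + 2k`.

**Daily fecundity.** A zero-inflated Poisson model per temperature group —
a day yields zero eggs with probability `p`, otherwise Poisson(`λ`) —
fitted by a purpose-built data-augmentation Gibbs sampler (Uniform prior
on `p`, Gaussian prior on `log λ`; default 7000 iterations, 4000 burn-in)
with the marginal zero probability `p + (1−p)e^(−λ)`, standardised
residuals, and pairwise group comparisons.

**Synthetic cohorts.** A seeded generator (`generate_cohort`,
`default_scenario`) reproduces the statistical structure of such
experiments — stage-structured mortality, right-skewed adult lifespan,
preoviposition delay, ZIP fecundity with > 90% zero days — so the entire
pipeline is testable without access to raw laboratory data.

## Worked example

```r
library(pestdemog)
report <- run_pipeline(list(quiet = TRUE))   # simulate 30/35/40 °C presets
report$demography[["30"]][c("R0", "r", "lambda", "T_gen", "DT")]
```

With the default seeds this prints (per-day rates, days):

```
30 °C: R0 7.50   r  0.0377   lambda 1.038   T 53.5   DT  18.4
35 °C: R0 4.42   r  0.0499   lambda 1.051   T 29.8   DT  13.9
40 °C: R0 0.29   r -0.0506   lambda 0.951   T 24.2   DT -13.7
```

So the simulated population grows at 30 and 35 °C (R0 > 1, r > 0) and
collapses at 40 °C (R0 < 1, negative r, negative doubling time = a halving
time), mirroring the sign pattern of the laboratory study this design
emulates. The bootstrap block attaches percentile CIs, e.g. at 30 °C
`R0 7.50 (3.61–11.34)`, `r 0.038 (0.024–0.046)`. The report also carries
the Brière fit of r against temperature (anchored at 17.2 °C where no
development occurs), the KM/AFT tables (lognormal wins the censored
first-egg endpoint on the presets, as it does on the real data), and the
per-group ZIP posteriors — at 30 °C the posterior zero probability is
0.907 against an observed zero fraction of 0.910.

A subcommand CLI wraps the same pipeline:

```sh
inst/cli/demog all --config cfg.json --out results/ --seed 11
```

## Documentation

`vignettes/pestdemog-methods.Rmd` describes the generative model behind
the synthetic cohorts, every estimator and its numerical choices, and what
the test suite does and does not establish.
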