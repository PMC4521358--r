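---
title: "Model structure, calibration, and design choices"
author: "demogsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demogsim)
```

# The modelling problem

demogsim simulates a female population of a country undergoing rapid
demographic and socioeconomic transition — the motivating setting is India in
the 1990s and 2000s — stratified by single year of age (0 to an open-ended
110), urban/rural residence, educational attainment (E0: no schooling, E1:
1–5 years, E2: 6–12 years, E3: more than 12 years) and migration history.
Women age deterministically one year at a time and face annual competing
risks of death and rural–urban migration; births enter new cohorts at age 0.
Fertility, mortality, migration and educational attainment all carry linear
secular trends, because the package's central question is what such trends do
to health-policy projections that conventionally hold exposures fixed.

Three nested model variants of increasing complexity are supported:

* **v1** — age and residence only: fertility and mortality with trends,
  education pooled, no migration;
* **v2** — v1 plus education stratification: education-specific fertility,
  relative risks of death by education, and secular trends in the education
  composition of birth cohorts;
* **v3** — v2 plus rural-to-urban migration rates with their own education
  gradient and trends.

All three are strictly nested: with unit relative risks, education-invariant
fertility and zero migration, v2 and v3 reproduce v1's trajectory to
numerical precision (this is a tested invariant).

# Process models

## Fertility

Cumulative fertility by age follows the Gompertz–Pasupuleti curve

$$G(t) = F \left(\tfrac{1}{2}\right)^{r^{(t-a)/b}}, \qquad
  r = \frac{\log 0.95}{\log 0.05},$$

with $F$ the lifetime quantum (births per woman), $a$ the median age of
fertility and $b$ the length of the age interval over which cumulative
fertility rises from 5% to 95% of $F$. The annual age-specific rate is the
increment $G(t{+}1) - G(t)$. A linear secular trend acts on $F$ only, clamped
at zero: trending the quantum changes how many children are born but not the
timing shape, which is the most parsimonious reading of "a linear trend in
fertility"; $a$ and $b$ are time-invariant per stratum. The base of the
logarithms in $r$ is irrelevant (a ratio); natural logs are used.

Because the model tracks females only while fertility counts all births,
newborn girls are `fraction_female` (default 0.487) of births. Newborns take
their mother's residence at birth. Fertility applies at every age through the
curve increments — no hard reproductive-age window is imposed, since the
curve itself is effectively zero outside it.

## Mortality

Aggregate mortality is decomposed by education through relative risks
against the lowest-attainment reference category:

$$\mu_{\alpha,\rho,y} = \sum_\varepsilon p_{\alpha,\rho,\varepsilon,y}\,
  RR_{\rho,\varepsilon}\, \mu_{\alpha,\rho,\varepsilon=0,y},$$

which rearranges to give the reference-category rate
$\mu_{\varepsilon=0} = \mu / \sum_\varepsilon p_\varepsilon RR_\varepsilon$.
The reference-category log-rate follows a Lee–Carter-type surface — a
constant plus a calendar-year slope plus an age slope — fit separately per
residence within three age clusters: under-1, 1–10, over-10. Centering
constants (reference year at the simulation start, reference age at the
cluster midpoint) are a pure reparameterization chosen to decorrelate the
MCMC parameters.

One structural choice deserves emphasis: the reference category is
*per residence* ($RR_{\rho,E0} = 1$ for both urban and rural). With separate
Lee–Carter intercepts per residence, a single global reference would leave
the urban intercept and the urban-E0 relative risk jointly unidentified (only
their product would enter any rate). Urban/rural level differences therefore
live in the intercepts, and cross-residence relative-risk presentations can
be derived as products. Relative risks are age-invariant within residence,
and — because education is assigned once at birth — they apply at all ages.

## Migration and the lookback bookkeeping

Rural-to-urban migration is an annual hazard per education category with a
linear trend, clamped to $[0,1]$. The structure carries both directions, but
the default parameterization pins the urban-to-rural rate at zero (a net-rate
reading); migrants keep their age and education and use destination-stratum
rates from the next simulated year.

Survey-style migration targets are lookback proportions: the share of a
stratum that moved within the last 6 years, 12 years, or ever. The state
therefore tracks an exact single-year years-since-move counter (capped at
12+) together with the direction of the last move; the 6- and 12-year bin
boundaries align exactly with the lookback windows, and a property test
checks the binning against an explicit per-individual history.

## Educational attainment

Education is fixed at birth. Each birth cohort receives a 4-category
distribution that drifts linearly in birth year (truncate-and-renormalize
keeps it on the simplex; the constraint handling is a design choice). Because
attainment has plateaued by ages 20–24, the prevalence among 20–24-year-olds
in a survey year mirrors the distribution of the cohort born about 22 years
earlier.

This creates an identifiability subtlety: over a 1992–2008 horizon, women
aged 20–24 at any survey wave were born *before* the simulation starts, so a
trend acting only on simulated newborns could never be learned from the
prevalence targets. The package therefore applies the same birth-year
distribution when expanding the starting population: the input table fixes
counts by age and residence, and the education split of each pre-1992 cohort
comes from the active parameter set. Prevalence at 20–24 is still extracted
from simulated counts, and now identifies the trend. The baseline of the
distribution is anchored at the first survey wave's observed prevalence and
treated as a fixed input; only the trends are calibrated.

## Within-year ordering and competing risks

Hazards are translated to annual probabilities by the standard competing
risks identity: with total hazard $H$, event $i$ has probability
$(h_i/H)(1 - e^{-H})$ and survival $e^{-H}$; the probabilities sum to one
exactly. Within a year, death and migration are resolved jointly, survivors
age one year (and migration counters advance), and births are computed from
start-of-year exposures — so women who die during the year still contribute
their expected births. The literature this model style draws on does not pin
down the intra-year ordering; this choice is fixed, documented, and the
conservation identity $N(t{+}1) = N(t) - \text{deaths} + \text{births}$
holds to $10^{-9}$ relative in expected-value mode and exactly (in integers)
in stochastic mode.

Two execution modes share one state type: *expected-value* (deterministic
fractional flows) and *stochastic* (binomial/Poisson draws per stratum, with
a recorded seed). Calibration always runs in expected-value mode — the
likelihood stays smooth and a run is deterministic — while stochastic mode
serves replicate-uncertainty studies. A tested law-of-large-numbers check
keeps the two modes consistent: the mean of 200 stochastic replicates stays
within three standard errors of the expected-value trajectory.

# Targets and the likelihood

Calibration targets mirror five survey-extract classes, each with a point
estimate and a 95% interval: children-ever-born by age band, residence,
education and survey wave; annual probability-of-death series by age band and
residence; education prevalence at ages 20–24 by wave; migration lookback
proportions by wave, residence and education; and annual population sizes by
residence. Annual life-expectancy rows are carried as *validation only* and
never enter the likelihood.

The likelihood is independent Gaussian per target,
$\sigma = (\text{CI}_{high} - \text{CI}_{low})/3.92$, floored at
$\max(1\%|\hat y|, 10^{-8})$ so that degenerate zero-width intervals cannot
dominate. Proportions are fit on the natural scale. Model answers are
aligned row-by-row: children-ever-born uses the cumulative curve at the wave
year's effective quantum; death probabilities are $1 - e^{-h}$ averaged over
the age band with stratum-count weights; prevalence and lookback proportions
come from counts; period life expectancy closes the year's count-weighted
hazard schedule into a life table
($l(x{+}1) = l(x)e^{-h(x)}$, $L(x)$ trapezoidal, terminal $L = l/h$).

# Calibration, DIC, and model selection

The sampler is adaptive block random-walk Metropolis under wide uniform
priors (fertility quantum in (0.2, 10) births, median age in (10, 40) years,
rise interval in (1, 30) years, relative risks in (0.05, 2), slopes bounded
at roughly ten times a plausible annual change; the bounds are data, passed
to `calibrate()`, not code). Parameters are grouped into small blocks — one
per fertility stratum, per Lee–Carter cell, per relative-risk residence, per
education-trend residence, per migration category — visited cyclically, one
block per iteration; per-block proposal scales adapt toward a 28% acceptance
rate during burn-in (the first half) and are then frozen, which preserves the
chain's validity.

Chains start from a moment-matched heuristic fit to the targets themselves
(plateau and quantile landmarks of the children-ever-born curves; log-linear
regression of the death probabilities; wave-to-wave prevalence slopes;
lookback levels scaled by the population ratio), jittered by a small fraction
of each prior range per chain. At desk scale this matters: from arbitrary
prior draws the burn-in budget would be spent travelling, not mixing.
Convergence is monitored with the Gelman–Rubin potential scale reduction
(warning threshold 1.1); four chains are the desk default and ten mirror a
repeated-random-starts convention.

Model choice uses the deviance information criterion with the Spiegelhalter
decomposition: $p_D = \bar D - D(\bar\theta)$, where $D(\bar\theta)$ is
re-evaluated through the simulator at the pooled posterior mean (projected
into the prior bounds with a warning if it falls outside). Lower DIC wins,
ties go to the simpler variant, and a margin over 10 points is flagged as
meaningful.

# The synthetic study conditions

`make_truth()` fixes a ground-truth v3 parameter set chosen once to be
realistic for a high-fertility population entering the demographic
transition in 1992: lifetime births around 4.8 (rural, no schooling)
declining with education to 2.7 and about 20% lower in urban areas, with a
quantum trend of −0.045 births/woman/year; reference-category mortality
giving an aggregate life expectancy near 62.7 years in 1992 rising to 67.1 by
2007, with relative risks of death declining monotonically with education
(rural 1, 0.89, 0.72, 0.56; urban-internal 1, 0.83, 0.60, 0.41) and urban
baseline rates about 34% below rural; rural-to-urban migration rising from
0.4%/year (no schooling) to 1.4%/year (post-secondary) with gentle positive
trends; and education prevalence shifting away from no-schooling by about one
percentage point per year. The starting population is $10^5$ expected-value
women (the likelihood and all proportions are scale-free; population targets
are generated on the synthetic scale), with a smooth declining age pyramid
(2%/year growth discounted by start-year survivorship) and a 26% urban share.
Survey waves sit at 1993, 1999 and 2006 within a 1992–2008 horizon, echoing
a three-wave national survey spacing; mortality, population and
life-expectancy series are annual.

Noise: each calibration row is perturbed with Normal noise whose standard
deviation is the class's relative 95% CI half-width (5% for rates and
proportions, 2% for population sizes and life expectancy) divided by 1.96,
with small absolute floors so that near-zero rows remain informative;
education groups are renormalized to the simplex after perturbation; values
that must be non-negative are truncated at zero with a warning. Passing an
explicit noise level of zero disables the perturbation entirely, which is
what the zero-residual-optimum tests rely on.

What the generator does *not* emulate — survey design effects, clustering,
non-response, recall bias, male populations, sub-national heterogeneity —
bounds what green tests can show: they demonstrate that the estimation
machinery recovers the truth under the model's own assumptions, not that the
model is adequate for any particular country's data.

# Scenarios

`make_static()` freezes every trend at its start-year *level* (levels are
re-anchored first, so the frozen and dynamic models coincide exactly at the
start year) — the conventional fixed-exposure comparator.
`apply_primary_education_intervention()` moves, for rural birth cohorts from
the intervention year on, all no-schooling probability mass into the primary
category; the mass transfer preserves the simplex without renormalization.
The intervention deliberately acts *only* through the education-conditional
rates (mortality relative risks, education-specific fertility and migration);
that indirection is what produces its compound effects. It touches cohorts
born from the intervention year onward, since education is fixed at birth;
re-educating living cohorts would be a different intervention. All four
scenario arms (dynamic/static × with/without intervention) share the start
year, the same expanded initial state, and the seed, so a zero-effect
intervention reproduces its baseline arm draw for draw, and the
difference-in-differences life-expectancy series
$(LE_{dyn,int} - LE_{dyn}) - (LE_{stat,int} - LE_{stat})$ is noise-reduced.
Uncertainty bands come from repeated posterior draws (hundreds at desk scale;
the machinery accepts arbitrarily many).

# Numerical choices and degenerate inputs

* Age cap 110, open-ended and absorbing; the terminal life-table class closes
  with $L = l/h$ (or one further person-year when the terminal hazard is 0).
  The trapezoidal $L(x)$ places a floor of half a year on life expectancy
  under extreme hazards, and its discretization error grows quadratically in
  the hazard; against a daily-step integration oracle it stays within 0.2
  years for schedules up to about 0.15/year.
* The cumulative fertility curve saturates in double precision roughly 2.5
  rise-intervals above the median age and underflows to zero about 1.7 below
  it; increments are clamped at zero so rounding can never produce negative
  rates.
* Competing-risk survival uses `expm1`, and the no-event probability is
  defined as one minus the event probabilities, so the annual probabilities
  sum to one exactly.
* Inside the sampler, the likelihood is evaluated by a fast path that
  precomputes index maps and extraction plans and calls the compiled annual
  stepping core directly; it is asserted (by test) to equal the general
  object-based path to nine decimal places across variants.
* Problem sizes in the shipped tests are desk-scale choices: recovery runs
  use 4 chains × 20,000 block updates; the DIC-ordering study uses 10
  replicate seeds at 2 chains × 1,000 updates per variant, which is already
  decisive because a missing migration component misfits the lookback
  targets by orders of magnitude.

# Known limitations

* The Gaussian likelihood treats targets as independent; real survey extracts
  share sampling structure across rows.
* Expected-value calibration ignores demographic stochasticity in the
  likelihood; at $10^5$ persons this is negligible, at much smaller
  populations it would not be.
* The education trend is identified through the parameter-dependent starting
  population; with an externally fixed starting composition and a short
  horizon it would be weakly identified, and fits should be read accordingly.
* Fertility timing parameters ($a$, $b$) are assumed trend-free, and the
  quantum trend is shared across strata.
* Migration is net rural-to-urban by default; return migration beyond the
  direction-of-last-move flag, international migration, and intra-zone moves
  are out of scope, as are males and household structure.
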