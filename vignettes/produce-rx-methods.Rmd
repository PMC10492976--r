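---
title: "Methods: microsimulation cost-effectiveness of produce prescriptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsimulation cost-effectiveness of produce prescriptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(produceRx)
```

## The model

`produceRx` implements an individual-level, annual-cycle state-transition
microsimulation of a national produce prescription program for US adults
aged 40–79 with both diabetes and food insecurity. Each simulated person
carries a survey weight (the number of population persons they represent),
demographics, socioeconomic markers, and cardiometabolic risk factors (BMI,
HbA1c, fruit and vegetable intake, hypertension, CVD history). Every year
each person faces logistic annual probabilities of a first CHD event, a
first stroke, a recurrent CVD event, CVD death, and non-CVD death, each a
function of their current risk factors. The intervention shifts fruit and
vegetable intake (+0.80 servings/day), BMI (−0.36 kg/m²), and HbA1c (−0.63
points) while the person is enrolled, which lowers event risks through two
pathways: a log-linear diet–disease relative risk per serving of fruits and
vegetables, and the BMI/HbA1c coefficients of the risk equations. Benefits
cease entirely on disenrollment.

The analysis is *paired*: the identical cohort is simulated with and
without the program under common random numbers — every person, cycle, and
draw purpose consumes the same uniform variate in both arms — so
incremental outcomes (CVD events averted, QALYs gained, cost changes) are
free of between-arm Monte Carlo noise. With a truly null intervention the
two arms are bit-identical, which the test suite checks exactly.

## The synthetic cohort generator

No survey microdata ship with the package. Instead, the generator samples
cohorts from a distributional recipe whose defaults reproduce the published
baseline profile of the eligible population (6.5 million adults):

* **Continuous variables** use a latent-Gaussian (Gaussian copula)
  construction: a multivariate standard normal draw with a configurable
  correlation matrix is pushed through each variable's marginal quantile
  function. Age, BMI and HbA1c are truncated normals whose *underlying*
  parameters are moment-matched numerically so that the realized, bounded
  marginal has exactly the published mean and SD (a naive truncated
  N(58.2, 10.2) on [40, 79] would have mean 58.55, not 58.2). Fruit
  (0.86 ± 1.08 servings/day) and vegetables (1.30 ± 1.04) are gamma: their
  coefficient of variation exceeds what any lower-truncated normal can
  carry, and intake distributions are right-skewed in practice. The default
  dependence is a single mild correlation (0.2) between BMI and HbA1c; all
  entries are configurable.
* **CVD history** (30.0% marginal) is given a logistic tilt in age
  (default +0.04 log-odds per year) whose intercept is calibrated at
  generation time so the marginal holds. The four sub-flags (angina 15.8%,
  CHD 11.9%, MI 12.8%, stroke 9.1%) are drawn conditionally on CVD history
  with probabilities solved by fixed-point iteration so that rejection
  sampling — which guarantees every case carries at least one flag —
  reproduces the published marginals.
* **Insurance** percentages describe overlapping coverage and sum to
  112.2%; the generator needs a proper distribution, so they are
  renormalized proportionally (the raw values are retained as an
  attribute). This is a modeling choice, not a fact about the population:
  the true partition of overlapping payers is not recoverable from the
  published marginals.
* **Survey weights** are lognormal (sdlog 0.5) rescaled to sum to the
  represented total, 6.5 million. Only the weighted total is published;
  the shape is a plausible stand-in and weights enter the analysis purely
  as multipliers.

What the generator does *not* emulate: the survey's joint dependence
structure beyond the configured correlations, its design variance
(strata/PSU), and missing-data imputation (synthetic records are complete
by construction). Passing calibration tests therefore show that the
generator reproduces the published marginals, not that downstream results
match what the real microdata would give.

## Intervention effects

Study-level effects are pooled by DerSimonian–Laird random-effects
meta-analysis (`pool_random_effects()`), the conventional default for
"random effects meta-analysis"; alternative heterogeneity estimators are
out of scope. The shipped base case is the pooled triple
ΔF&V +0.80 (95% CI 0.45–1.15), ΔBMI −0.36 (−0.55, −0.16),
ΔHbA1c −0.63 (−0.98, −0.28). For uncertainty analysis each effect is
normal with SD = (CI upper − CI lower)/(2·1.96), the only distribution
recoverable from a printed mean and CI. The original 20 study-level rows
are not published in the main text; `synthetic_study_set()` generates
labelled fixtures for testing and demonstration.

## Risk equations and the diet pathway

The original model's transition equations live in unpublished companion
material. This package therefore defines logistic annual-probability
equations over the covariates the model names (age, sex, race or
ethnicity, BMI, HbA1c, hypertension, CVD history) and ships **synthetic
default coefficients** calibrated so that the implied rates are plausible
for this high-risk population: mean first-CVD probability about 1–3%/year
among those without CVD history, recurrent about 3–6%/year (asserted in
the test suite). They are configuration values, not estimates; every
acceptance-level claim about the package is structural
(calibration, identities, monotonicity), never an event-count
reproduction.

The diet pathway is log-linear: RR = exp(a · Δservings · ln r), with
default r = 0.95 per serving for CHD and 0.96 for stroke, and a banded age
attenuation a (1.0 below 60, 0.8 in the 60s, 0.6 in the 70s, 0.4 at 80+)
that shrinks the log-RR toward the null at older ages. Relative risks are
applied on the rate scale, p′ = 1 − (1 − p)^RR, which preserves 0 and 1,
is exact under proportional hazards within a cycle, and agrees with p·RR
to first order in small p. Recurrent events use the CHD relative risk
(a single pooled recurrent equation; most recurrent events in this
population are coronary). Non-CVD mortality is a synthetic Gompertz-shaped
life table (doubling time 8 years, female rates 25% lower, capped at 0.7),
again exposed as configuration.

Within a cycle the order is: risk-factor update → event draws → mortality
draws → accrual. Death precludes later same-cycle events; the death year
itself accrues its costs and utility, all later years accrue nothing.
Whether the original engine updates risk factors before or after the
event draws is unstated; this engine fixes update-first, which makes the
intervention affect risks from the first enrolled year.

## Costs, utilities, discounting

* **Intervention costs.** Food cost accrues at the redeemed value,
  $32/person/month ($384/year); the offered value ($42/month, $504/year)
  is retained for reporting. Administration is 50% of food cost in program
  year 1 (launch premium — exactly one third of total program cost) and
  `food · s/(1−s)` thereafter so the steady-state admin share is exactly
  `s` (default 15%; presets 8% and 21.3%). The launch premium applies in
  calendar year 1 of the program, not per-enrollee year 1.
* **Health-care costs** are a linear prediction over age, sex, race or
  ethnicity, BMI, diabetes, hypertension and CVD history, plus an HbA1c
  slope ($1000/point above 7% by default) that enters only the non-CVD
  diabetes component — the guard against double counting, since averted
  CVD events already remove CVD-dependent costs through the CVD-history
  coefficient and acute-event costs. Coefficients are synthetic stand-ins
  on a plausible 2021-USD scale.
* **Utilities** are a linear EQ-5D-style prediction clamped to [0, 1],
  with one-year decrements of 0.055 (acute CHD) and 0.3 (acute stroke) in
  the event year only.
* **Productivity costs** accrue per prevalent CHD and stroke case per
  year, additively.
* **Discounting** is 3%/year with the first year undiscounted
  (`amount/(1+r)^(t−1)`); the original timing convention is unstated, so
  this one is fixed and documented.

## Cost-effectiveness analysis

Net cost from the health-care perspective is intervention cost minus
health-care savings; the societal perspective further subtracts
productivity savings. ICERs are ratios of means (mean net cost over mean
QALYs gained across PSA draws), with dominance labels ("cost-saving" when
QALYs are gained at negative net cost).

The PSA redraws every uncertain parameter per draw: the three effects from
their CI-derived normals, diet RRs lognormally on the log scale, cost and
utility scale factors as truncated-normal multipliers (`psa_config()`).
Parameter draws use per-draw substreams of the base seed; the simulated
event streams are *common across draws*, so between-draw variance isolates
parameter uncertainty. Cohort sampling uncertainty enters as the
within-draw variance of the survey-weighted incremental total (treating
weighted person-level contributions as an iid, with-replacement sample),
and Rubin's rule combines the two: total variance = mean within-draw
variance + (1 + 1/m) × between-draw variance. A design in which each draw
also re-randomizes events would fold simulation noise into the
between-draw term and double-count it against the within-draw component.

The one-way sweep moves all three effects jointly to the same percentile
of their distributions, on the *benefit* scale: the 2.5th percentile is
the least favorable triple (+0.45, −0.16, −0.28), the 97.5th the most
favorable. The threshold analysis exploits the fact that program costs do
not feed back into health states: with outcomes frozen, the ICER is
monotone in the total monthly cost (redeemed food + administration), and
bisection finds the break-even monthly cost to $0.10. The closed-form
solution ((WTP·ΔQALY + savings)/C₀, rescaled) serves as the independent
oracle in the tests.

## Numerical choices and degenerate inputs

* Moment matching for truncated normals minimizes squared relative moment
  error with `optim` (tolerance 1e-15 on the objective); a spec whose
  target moments are infeasible under truncation raises an error rather
  than silently drifting.
* Zero SDs are honored exactly: degenerate marginals return their means,
  degenerate CIs make every effect draw equal the mean.
* Dependence matrices must be symmetric PSD (eigenvalue check at −1e-8);
  category probabilities must sum to 1 within 1e-9.
* Within a cycle, a first CHD event takes precedence over a first stroke
  drawn in the same year (at most one first event per year); conditional
  on a recurrent event, the residual uniform `u/p` resolves its CHD/stroke
  type so the type split (default 60% CHD) shares randomness across arms.
* All generators and the engine restore the caller's RNG state, so
  package calls do not perturb surrounding seeded code.

## Problem sizes

The package's own validation uses cohorts of 50,000 for generator
calibration (weighted moments within 3 Monte Carlo standard errors;
categorical marginals within 1.5 points), 2,000–5,000 persons for engine
properties, and 100-draw PSAs for monotonicity of the acceptability
curve; the full analysis configuration (1000 draws) is the shipped
default in `default_config()`. These sizes were chosen so the complete
suite exercises every property at comfortable Monte Carlo resolution.

## Limitations

The risk, cost and utility coefficients are synthetic stand-ins, so
absolute event counts, dollar totals and ICERs produced by the defaults
characterize the *machinery*, not the published national estimates — those
require the original survey microdata and unpublished model equations.
No within-year event timing, no half-cycle correction (annual accrual at
cycle end), no family spillover effects, no institutional/nursing-home
cost component, and no churn in the 50%-participation scenario
(participants are fixed at baseline). Diabetes incidence is inert because
every baseline record already has diabetes, though the state exists in
the engine.
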