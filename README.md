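# produceRx

Individual-level state-transition microsimulation and cost-effectiveness
analysis of **produce prescription programs** — health-care-based provision
of free fruits and vegetables — for US adults aged 40–79 with both diabetes
and food insecurity.

Produce prescriptions raise fruit and vegetable intake and improve
cardiometabolic risk factors in trials and quasi-experimental studies. The
policy question this package addresses is what a *national* program would
do over 5 years, 10 years, and a lifetime: how many cardiovascular disease
(CVD) events it would avert, how many quality-adjusted life-years (QALYs)
it would generate, what it would cost, and whether it would be cost
effective at conventional willingness-to-pay thresholds.

## What the package does

* **Synthetic eligible cohorts** (`default_table1_spec()`,
  `generate_cohort()`): survey-weighted populations whose marginals
  reproduce the published baseline profile of the 6.5 million eligible US
  adults (age 58.2 ± 10.2 y, BMI 33.6 ± 7.95 kg/m², HbA1c 7.3 ± 1.95%,
  30.0% with CVD history, …), built from a latent-Gaussian copula with
  moment-matched truncated-normal and gamma marginals.
* **Intervention effects** (`pool_random_effects()`,
  `intervention_effects()`): DerSimonian–Laird random-effects pooling of
  study-level effects; base case ΔF&V +0.80 servings/day (95% CI
  0.45–1.15), ΔBMI −0.36 kg/m², ΔHbA1c −0.63 points, with benefits ceasing
  on disenrollment.
* **Risk engine** (`annual_probability()`, `rr_from_delta()`,
  `adjust_probability()`): logistic annual transition probabilities for
  first CHD/stroke, recurrent CVD, CVD death and non-CVD death;
  a log-linear diet–disease relative risk per serving (RR 0.95 CHD / 0.96
  stroke, attenuating with age) applied on the rate scale,
  p′ = 1 − (1 − p)^RR.
* **Costs and utilities** (`intervention_cost()`,
  `annual_healthcare_cost()`, `annual_utility()`): $32/month redeemed food
  value, administration 15% of total program cost in steady state (50% of
  food cost in the launch year), individually predicted health-care costs
  with an HbA1c term restricted to non-CVD diabetes costs, acute-event and
  productivity costs, EQ-5D-style utilities with event-year decrements
  (−0.055 CHD, −0.3 stroke), 3% annual discounting.
* **Paired engine** (`run_paired()`, `aggregate_paired()`,
  `subgroup_aggregate()`): the same cohort simulated with and without the
  program under common random numbers, up to 60 annual cycles or death.
* **CEA** (`icer()`, `run_psa()`, `rubins_combine()`, `ceac()`,
  `one_way_sweep()`, `threshold_monthly_cost()`): net costs from
  health-care and societal perspectives,
  ICER = Δcost/ΔQALY, probabilistic sensitivity analysis with
  Rubin's-rule 95% uncertainty intervals, cost-effectiveness acceptability
  curves at $50,000 and $150,000/QALY, effect-percentile sweeps, and the
  break-even monthly program cost.

The risk, health-care-cost and utility coefficients shipped as defaults
are synthetic stand-ins on plausible US scales (the originals are
unpublished); the vignette in `vignettes/produce-rx-methods.Rmd` documents
every modeling choice.

## Worked example

```r
library(produceRx)

cohort <- generate_cohort(default_table1_spec(), n = 5000, seed = 42)
sim    <- run_paired(cohort, seed = 42)      # base-case effects and costs
results_table(sim)
```

```
                        outcome horizon_5 horizon_10 horizon_lifetime
1      total_cvd_events_averted  1.42e+05   2.95e+05         7.24e+05
2       first_cvd_cases_averted  4.73e+04   1.01e+05         9.54e+04
3  recurrent_cvd_events_averted  9.45e+04   1.94e+05         6.28e+05
4                  qalys_gained  7.44e+04   1.91e+05         7.08e+05
5       healthcare_cost_savings  1.15e+10   2.06e+10         3.24e+10
6     productivity_cost_savings  1.63e+08   5.71e+08         1.85e+09
7       intervention_food_costs  1.13e+10   1.98e+10         3.59e+10
8      intervention_admin_costs  2.80e+09   4.30e+09         7.14e+09
9           net_cost_healthcare  2.59e+09   3.46e+09         1.06e+10
10            net_cost_societal  2.43e+09   2.89e+09         8.75e+09
11              icer_healthcare  3.48e+04   1.82e+04         1.50e+04
12                icer_societal  3.26e+04   1.52e+04         1.24e+04
```

Rows 1–4 are population totals (the 5,000 simulated persons carry survey
weights summing to 6.5 million adults), rows 5–10 are discounted 2021
dollars, and the last two rows are incremental cost-effectiveness ratios
in $/QALY: under the synthetic default equations the program costs about
$15,000 per QALY gained over a lifetime from the health-care perspective —
cheaper per QALY at longer horizons, as event-driven savings accumulate
against front-loaded program costs.

```r
thr <- threshold_monthly_cost(sim, wtp = 150000)
# break-even total monthly cost: $121.28 (default $37.65)
```

With the frozen simulation, the program stays under $150,000/QALY until
total monthly spending (redeemed food + administration) exceeds
$121.28/person — the bisection answer agrees with the closed-form
break-even cost to $0.10.

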