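cohort_small <- generate_cohort(default_table1_spec(), 300, seed = 21)

test_that("zero effects and zero costs make the two arms exactly identical", {
  sim <- run_paired(cohort_small, null_effects(),
                    cost_pars = zero_cost_params(), seed = 4)
  for (fld in names(sim$policy)) {
    expect_identical(sim$policy[[fld]], sim$control[[fld]])
  }
  ag <- aggregate_paired(sim, "lifetime")
  expect_identical(ag$total_cvd_averted, 0)
  expect_identical(ag$qalys_gained, 0)
  expect_identical(ag$net_cost_healthcare, 0)
  expect_identical(ag$net_cost_societal, 0)
  # common-random-number sharpness: per-person variance exactly zero
  expect_identical(var(ag$per_person$qaly), 0)
})

test_that("repeated runs with the same seed are identical", {
  a <- run_paired(cohort_small, seed = 8)
  b <- run_paired(cohort_small, seed = 8)
  expect_identical(a$policy, b$policy)
  expect_identical(a$control, b$control)
  expect_identical(a$enrolled, b$enrolled)
})

test_that("protective effects avert first CVD events in aggregate", {
  co <- generate_cohort(default_table1_spec(), 5000, seed = 33)
  sim <- run_paired(co, seed = 12)
  first_pol <- sum(sim$policy$first_chd) + sum(sim$policy$first_stroke)
  first_ctl <- sum(sim$control$first_chd) + sum(sim$control$first_stroke)
  expect_lt(first_pol, first_ctl)
  ag <- aggregate_paired(sim, "lifetime")
  expect_gt(ag$qalys_gained, 0)
  # alive person-years not reduced by a protective intervention
  expect_gte(sum(sim$policy$alive), sum(sim$control$alive))
})

test_that("death absorbs: no costs, utility or events after the death year", {
  sim <- run_paired(cohort_small, seed = 5)
  for (led in list(sim$policy, sim$control)) {
    death_year <- apply(led$cvd_death | led$other_death, 1,
                        function(z) if (any(z)) which(z)[1] else NA_integer_)
    for (i in which(!is.na(death_year))) {
      after <- seq_len(ncol(led$alive)) > death_year[i]
      expect_false(any(led$alive[i, after]))
      expect_equal(sum(led$utility[i, after]), 0)
      expect_equal(sum(led$cost_healthcare[i, after] +
                         led$cost_int_food[i, after] +
                         led$cost_acute[i, after]), 0)
      expect_false(any(led$first_chd[i, after] | led$recurrent[i, after]))
    }
    # first events happen at most once per person
    expect_lte(max(rowSums(led$first_chd + led$first_stroke)), 1)
    # recurrent events require pre-existing CVD history at baseline or a
    # prior first event
    rec_rows <- which(rowSums(led$recurrent) > 0)
    for (i in rec_rows) {
      t_rec <- which(led$recurrent[i, ])[1]
      t_first <- which(led$first_chd[i, ] | led$first_stroke[i, ])
      expect_true(cohort_small$cvd_history[i] ||
                    (length(t_first) && t_first[1] < t_rec))
    }
  }
})

test_that("aggregation is internally consistent and horizon-bounded", {
  sim <- run_paired(cohort_small, seed = 9)
  ag <- aggregate_paired(sim, "lifetime")
  expect_equal(ag$total_cvd_averted,
               ag$first_cvd_averted + ag$recurrent_cvd_averted)
  expect_equal(ag$net_cost_healthcare,
               ag$intervention_cost_total - ag$healthcare_savings)
  expect_equal(ag$net_cost_societal,
               ag$net_cost_healthcare - ag$productivity_savings)
  # the population scale is carried by the survey weights
  expect_equal(ag$population, 6.5e6, tolerance = 1e-6)
  expect_equal(ag$cvd_averted_per_100k, 1e5 * ag$total_cvd_averted / 6.5e6)
  expect_error(aggregate_paired(sim, 61), "horizon")
  # per-person first-event differences are bounded by one event either way
  ag5 <- aggregate_paired(sim, 5)
  expect_true(all(abs(ag5$per_person$first) <= 1))
  expect_equal(ag5$population, ag$population)
})

test_that("undiscounted totals dominate discounted totals", {
  sim <- run_paired(cohort_small, seed = 14)
  d <- aggregate_paired(sim, "lifetime", discount_rate = 0.03)
  u <- aggregate_paired(sim, "lifetime", discount_rate = 0)
  expect_lt(d$intervention_cost_total, u$intervention_cost_total)
})

test_that("subgroup results partition the overall results", {
  sim <- run_paired(cohort_small, seed = 6)
  ag <- aggregate_paired(sim, "lifetime")
  by_sex <- subgroup_aggregate(sim, "sex")
  expect_equal(sum(by_sex$qalys_gained), ag$qalys_gained, tolerance = 1e-8)
  expect_equal(sum(by_sex$total_cvd_averted), ag$total_cvd_averted,
               tolerance = 1e-8)
  by_ins <- subgroup_aggregate(sim, "insurance")
  expect_equal(nrow(by_ins), 5)
  expect_equal(sum(by_ins$population), 6.5e6, tolerance = 1e-6)
  expect_equal(sum(by_ins$net_cost_societal), ag$net_cost_societal,
               tolerance = 1e-8)
  expect_error(subgroup_aggregate(sim, "shoe_size"), "unknown stratifier")
})

test_that("participation below one splits the cohort reproducibly", {
  sim <- run_paired(cohort_small, scenario = list(participation_fraction = 0.5),
                    seed = 19)
  expect_gt(mean(sim$enrolled), 0.35)
  expect_lt(mean(sim$enrolled), 0.65)
  # non-participants accrue no intervention cost and identical outcomes
  out <- which(!sim$enrolled)
  expect_equal(sum(sim$policy$cost_int_food[out, ]), 0)
  expect_identical(sim$policy$utility[out, ], sim$control$utility[out, ])
})

test_that("the ledger flattens to a long person-year table", {
  sim <- run_paired(cohort_small[1:20, ], seed = 2)
  df <- ledger_df(sim, "policy")
  expect_equal(nrow(df), 20 * 60)
  expect_true(all(c("person_id", "year", "arm", "alive", "utility",
                    "cost_healthcare") %in% names(df)))
  expect_equal(unique(df$arm), "policy")
})
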