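test_that("ICER computation returns ratios and dominance labels", {
  r <- icer(4.72e9, 260000)
  expect_equal(r$label, "icer")
  expect_equal(r$value, 4.72e9 / 260000, tolerance = 1e-12)
  expect_equal(r$value, 18153.85, tolerance = 1e-3)
  expect_equal(icer(-0.049e9, 260000)$label, "cost-saving")
  expect_equal(icer(5e9, -1000)$label, "dominated")
  expect_equal(icer(0, 0)$label, "undefined")
  expect_equal(icer(-10, -5)$value, 2)  # fewer QALYs at savings: still a ratio
})

test_that("Rubin's rule combines within- and between-draw variance", {
  same <- rubins_combine(c(2, 2, 2), c(0.5, 0.5, 0.5))
  expect_equal(same$total_variance, 0.5)
  expect_equal(same$mean, 2)
  two <- rubins_combine(c(0, 2), c(0, 0))
  expect_equal(two$total_variance, (1 + 1 / 2) * 2)
  # randomized instances vs direct transcription
  set.seed(99)
  for (i in 1:10) {
    m <- sample(3:12, 1)
    pts <- rnorm(m); wv <- runif(m)
    r <- rubins_combine(pts, wv)
    total <- mean(wv) + (1 + 1 / m) * sum((pts - mean(pts))^2) / (m - 1)
    expect_equal(r$total_variance, total, tolerance = 1e-12)
    expect_gte(r$total_variance, mean(wv))
    expect_equal(r$ui95, mean(pts) + c(-1.96, 1.96) * sqrt(total),
                 tolerance = 1e-12)
  }
  expect_error(rubins_combine(1, 1), "at least 2")
})

test_that("the acceptability curve is a step in WTP with the right limits", {
  draws <- data.frame(qalys_gained = 1, net_cost_healthcare = 1e5,
                      net_cost_societal = 1e5)
  cc <- ceac(draws, c(50000, 150000))
  expect_equal(cc$p_cost_effective, c(0, 1))
  saving <- data.frame(qalys_gained = c(1, 2),
                       net_cost_healthcare = c(-5, -10),
                       net_cost_societal = c(-5, -10))
  expect_equal(ceac(saving, c(0, 50000, 1e12))$p_cost_effective, c(1, 1, 1))
  mixed <- data.frame(qalys_gained = c(1, 1, -1),
                      net_cost_healthcare = c(1e4, 2e5, 1e4),
                      net_cost_societal = c(1e4, 2e5, 1e4))
  # WTP -> infinity: probability equals the fraction of draws gaining QALYs
  expect_equal(ceac(mixed, 1e12)$p_cost_effective, 2 / 3)
  grid <- ceac(mixed, c(0, 1e4, 5e4, 1e5, 5e5, 1e12))$p_cost_effective
  expect_true(all(diff(grid) >= -1e-12))
})

test_that("PSA is reproducible, centered on benefit, and accounting-consistent", {
  co <- generate_cohort(default_table1_spec(), 400, seed = 55)
  p1 <- run_psa(co, n_draws = 6, base_seed = 77, horizon = 10)
  p2 <- run_psa(co, n_draws = 6, base_seed = 77, horizon = 10)
  expect_identical(p1$draws, p2$draws)
  expect_gt(mean(p1$draws$qalys_gained > 0), 0.5)
  expect_equal(p1$draws$net_cost_healthcare,
               p1$draws$intervention_cost_total - p1$draws$healthcare_savings,
               tolerance = 1e-9)
  expect_equal(p1$draws$net_cost_societal,
               p1$draws$net_cost_healthcare - p1$draws$productivity_savings,
               tolerance = 1e-9)
  expect_gte(p1$combined$qalys_gained$total_variance, 0)
  expect_error(run_psa(co, n_draws = 1, base_seed = 1), "n_draws")
})

test_that("degenerate PSA with all parameter SDs zero repeats the base case", {
  co <- generate_cohort(default_table1_spec(), 200, seed = 42)
  eff <- intervention_effects(
    delta_fv = list(mean = 0.8, ci95 = c(0.8, 0.8)),
    delta_bmi = list(mean = -0.36, ci95 = c(-0.36, -0.36)),
    delta_hba1c = list(mean = -0.63, ci95 = c(-0.63, -0.63)))
  frozen <- psa_config(rr_log_sd = 0, cost_mult_sd = 0, hc_mult_sd = 0,
                       util_dec_sd = 0)
  p <- run_psa(co, eff, n_draws = 3, base_seed = 5, horizon = 5,
               psa_cfg = frozen)
  # degenerate distributions: every draw is the same analysis
  per_draw <- p$draws[, setdiff(names(p$draws), "draw")]
  expect_equal(per_draw[2, ], per_draw[1, ], ignore_attr = TRUE)
  expect_equal(per_draw[3, ], per_draw[1, ], ignore_attr = TRUE)
})

test_that("cost side scales linearly without feeding back into health", {
  co <- generate_cohort(default_table1_spec(), 250, seed = 13)
  base <- run_paired(co, cost_pars = cost_params(), seed = 3)
  double <- run_paired(co, cost_pars = cost_params(monthly_redeemed = 64),
                       seed = 3)
  ab <- aggregate_paired(base, "lifetime")
  ad <- aggregate_paired(double, "lifetime")
  expect_equal(ad$intervention_food_cost, 2 * ab$intervention_food_cost,
               tolerance = 1e-9)
  expect_equal(ad$qalys_gained, ab$qalys_gained, tolerance = 1e-12)
  expect_equal(ad$total_cvd_averted, ab$total_cvd_averted, tolerance = 1e-12)
})

test_that("threshold analysis matches the algebraic break-even cost", {
  co <- generate_cohort(default_table1_spec(), 500, seed = 23)
  sim <- run_paired(co, seed = 31)
  ag <- aggregate_paired(sim, "lifetime")
  thr <- threshold_monthly_cost(sim, wtp = 150000)
  # algebra: costs enter linearly, so the break-even scale solves
  # (f * C0 - savings) / dQALY = WTP
  f_star <- (150000 * ag$qalys_gained + ag$healthcare_savings) /
    ag$intervention_cost_total
  expect_equal(thr$threshold_monthly, f_star * thr$default_monthly,
               tolerance = 0.10)
  # halving the WTP strictly lowers the threshold
  thr50 <- threshold_monthly_cost(sim, wtp = 75000)
  expect_lt(thr50$threshold_monthly, thr$threshold_monthly)
  # an unattainable WTP reports an unbounded threshold
  expect_equal(threshold_monthly_cost(sim, wtp = 1e15)$threshold_monthly, Inf)
})

test_that("results table reports all outcomes across horizons", {
  co <- generate_cohort(default_table1_spec(), 200, seed = 61)
  sim <- run_paired(co, seed = 7)
  tab <- results_table(sim)
  expect_equal(ncol(tab), 4)
  expect_true("total_cvd_events_averted" %in% tab$outcome)
  r <- tab[tab$outcome == "total_cvd_events_averted", ]
  expect_lte(abs(r$horizon_5), abs(r$horizon_lifetime))
})
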