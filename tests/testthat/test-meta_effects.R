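test_that("single-study and homogeneous pooling reduce to closed forms", {
  one <- data.frame(study_id = "s1", outcome = "bmi", estimate = 0.5,
                    standard_error = 0.1)
  res <- pool_random_effects(one)
  expect_equal(res$pooled_mean, 0.5)
  expect_equal(res$tau2, 0)
  two <- data.frame(study_id = c("s1", "s2"), outcome = "bmi",
                    estimate = c(0.8, 0.8), standard_error = c(0.2, 0.2))
  res2 <- pool_random_effects(two)
  expect_equal(res2$pooled_mean, 0.8)
  expect_equal(res2$tau2, 0)
  expect_equal(res2$pooled_se, 0.2 / sqrt(2))
})

test_that("DerSimonian-Laird pooling matches the brute-force oracle and metafor", {
  studies <- data.frame(study_id = c("a", "b", "c"), outcome = "fv_servings",
                        estimate = c(0.2, 0.9, 1.4),
                        standard_error = c(0.15, 0.2, 0.3))
  res <- pool_random_effects(studies)
  oracle <- dl_oracle(studies$estimate, studies$standard_error)
  expect_equal(res$pooled_mean, oracle$mu, tolerance = 1e-10)
  expect_equal(res$pooled_se, oracle$se, tolerance = 1e-10)
  expect_equal(res$tau2, oracle$tau2, tolerance = 1e-10)
  # randomized small instances against the oracle
  set.seed(41)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    y <- rnorm(k); se <- runif(k, 0.05, 0.5)
    st <- data.frame(study_id = seq_len(k), outcome = "hba1c",
                     estimate = y, standard_error = se)
    r <- pool_random_effects(st)
    o <- dl_oracle(y, se)
    expect_equal(r$pooled_mean, o$mu, tolerance = 1e-10)
    expect_equal(r$tau2, o$tau2, tolerance = 1e-10)
  }
  skip_if_not_installed("metafor")
  m <- metafor::rma(yi = studies$estimate, sei = studies$standard_error,
                    method = "DL")
  expect_equal(res$pooled_mean, as.numeric(m$beta), tolerance = 1e-8)
  expect_equal(res$tau2, m$tau2, tolerance = 1e-8)
})

test_that("pooling rejects mixed outcomes and empty input", {
  mixed <- data.frame(study_id = c("a", "b"), outcome = c("bmi", "hba1c"),
                      estimate = c(1, 1), standard_error = c(0.1, 0.1))
  expect_error(pool_random_effects(mixed), "outcome")
  expect_error(pool_random_effects(mixed[0, ]), "no studies")
})

test_that("pooled SE beats the most precise study under homogeneity", {
  set.seed(7)
  se <- runif(5, 0.1, 0.3)
  st <- data.frame(study_id = 1:5, outcome = "bmi",
                   estimate = rep(0.4, 5), standard_error = se)
  res <- pool_random_effects(st)
  expect_equal(res$tau2, 0)
  expect_lt(res$pooled_se, min(se))
})

test_that("effect uncertainty SDs are recovered from the printed CIs", {
  eff <- default_intervention_effects()
  expect_equal(eff$effects$fv_servings$sd, (1.15 - 0.45) / (2 * 1.96))
  expect_equal(eff$effects$fv_servings$mean, 0.80)
  expect_equal(eff$effects$bmi$mean, -0.36)
  expect_equal(eff$effects$hba1c$mean, -0.63)
  expect_error(intervention_effects(delta_fv = list(mean = 2, ci95 = c(0.45, 1.15))),
               "bracket")
})

test_that("effect sampler is seeded, centered, and degenerates with the CI", {
  eff <- default_intervention_effects()
  d1 <- effect_sampler(eff, 100, seed = 5)
  d2 <- effect_sampler(eff, 100, seed = 5)
  expect_identical(d1, d2)
  big <- effect_sampler(eff, 10000, seed = 11)
  se_mc <- eff$effects$hba1c$sd / sqrt(10000)
  expect_lt(abs(mean(big$hba1c) - (-0.63)), 3 * se_mc)
  degen <- intervention_effects(delta_fv = list(mean = 0.8, ci95 = c(0.8, 0.8)))
  expect_equal(effect_sampler(degen, 50, seed = 1)$fv_servings, rep(0.8, 50))
})

test_that("effect percentiles hit the CI bounds and are monotone", {
  eff <- default_intervention_effects()
  expect_equal(effect_percentile(eff, "fv_servings", 0.5), 0.80)
  expect_equal(effect_percentile(eff, "fv_servings", 0.025), 0.45,
               tolerance = 1e-4)
  expect_equal(effect_percentile(eff, "fv_servings", 0.975), 1.15,
               tolerance = 1e-4)
  p <- seq(0.05, 0.95, by = 0.05)
  q <- vapply(p, function(x) effect_percentile(eff, "bmi", x), numeric(1))
  expect_true(all(diff(q) > 0))
  expect_error(effect_percentile(eff, "fv_servings", 0), "percentile")
  expect_error(effect_percentile(eff, "fv_servings", 1.2), "percentile")
})

test_that("synthetic study sets pool near their generating mean", {
  st <- synthetic_study_set(k = 12, true_mean = 0.8, tau = 0.15, seed = 2)
  res <- pool_random_effects(st)
  expect_equal(res$k, 12)
  expect_lt(abs(res$pooled_mean - 0.8), 4 * res$pooled_se)
  ft <- forest_table(st)
  expect_length(ft, 13)
  expect_match(ft[13], "RE pooled")
})
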