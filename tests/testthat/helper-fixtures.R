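# shared fixtures: tiny hand-built cohorts and degenerate parameter sets

# one fully specified individual record; override fields via ...
make_person <- function(person_id = "p1", survey_weight = 1, age = 60,
                        sex = "female", race_ethnicity = "NH-White",
                        education = "HS/GED", income_poverty_ratio = "<1.30",
                        insurance = "medicaid", food_insecure = TRUE,
                        diabetes = TRUE, hypertension = FALSE,
                        cvd_history = FALSE, angina = FALSE, chd = FALSE,
                        mi = FALSE, stroke = FALSE, bmi = 30, hba1c = 7,
                        fruit_servings = 0.86, veg_servings = 1.30) {
  data.frame(person_id = person_id, survey_weight = survey_weight, age = age,
             sex = sex, race_ethnicity = race_ethnicity,
             education = education,
             income_poverty_ratio = income_poverty_ratio,
             insurance = insurance, food_insecure = food_insecure,
             diabetes = diabetes, hypertension = hypertension,
             cvd_history = cvd_history, angina = angina, chd = chd, mi = mi,
             stroke = stroke, bmi = bmi, hba1c = hba1c,
             fruit_servings = fruit_servings, veg_servings = veg_servings,
             stringsAsFactors = FALSE)
}

make_cohort <- function(...) do.call(rbind, list(...))

# zero-cost parameter set for paired-null scenarios
zero_cost_params <- function() {
  cost_params(monthly_offered = 0, monthly_redeemed = 0,
              acute_cost_chd = 0, acute_cost_stroke = 0,
              productivity_chd = 0, productivity_stroke = 0,
              hba1c_cost_slope = 0)
}

# intervention effects that are exactly null (degenerate CIs)
null_effects <- function() {
  intervention_effects(delta_fv = list(mean = 0, ci95 = c(0, 0)),
                       delta_bmi = list(mean = 0, ci95 = c(0, 0)),
                       delta_hba1c = list(mean = 0, ci95 = c(0, 0)))
}

# weighted mean and its Monte-Carlo standard error for a cohort column
weighted_mean_se <- function(x, w) {
  m <- sum(w * x) / sum(w)
  se <- sqrt(sum((w * (x - m))^2)) / sum(w)
  c(mean = m, se = se)
}

# brute-force DerSimonian-Laird transcription, independent of the package
dl_oracle <- function(y, se) {
  k <- length(y)
  w_fe <- 1 / se^2
  mu_fe <- sum(w_fe * y) / sum(w_fe)
  Q <- sum(w_fe * (y - mu_fe)^2)
  c_dl <- sum(w_fe) - sum(w_fe^2) / sum(w_fe)
  tau2 <- max(0, (Q - (k - 1)) / c_dl)
  w_re <- 1 / (se^2 + tau2)
  mu <- sum(w_re * y) / sum(w_re)
  list(mu = mu, se = sqrt(1 / sum(w_re)), tau2 = tau2)
}
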