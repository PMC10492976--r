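#' Annual-probability risk equations
#'
#' Each transition (first CHD, first stroke, recurrent CVD, CVD death,
#' non-CVD death) is governed by a logistic annual-probability equation over
#' the individual-level covariates the model tracks: age, sex, race or
#' ethnicity, BMI, HbA1c, hypertension and CVD history. Continuous covariates
#' enter centered at reference values so intercepts are interpretable as the
#' annual probability for a reference individual.
#'
#' The default coefficients shipped by [default_risk_config()] are synthetic
#' stand-ins calibrated to plausible US event rates in this high-risk
#' population (first CVD roughly 1-3%/year, recurrent 3-6%/year); they are
#' configuration, not estimates, and users may override any of them.
#'
#' @param intercept log-odds intercept (annual scale).
#' @param coef named numeric vector of coefficients; recognized names are
#'   `age` (per year, centered at 60), `male`, `race_NH-Black`,
#'   `race_Hispanic`, `race_Other`, `bmi` (per kg/m², centered at 30),
#'   `hba1c` (per point, centered at 7), `hypertension`, `cvd_history`.
#' @return An object of class `risk_equation`.
#' @export
risk_equation <- function(intercept, coef = numeric()) {
  known <- c("age", "male", "race_NH-Black", "race_Hispanic", "race_Other",
             "bmi", "hba1c", "hypertension", "cvd_history")
  bad <- setdiff(names(coef), known)
  if (length(bad)) stop("unknown coefficient(s): ", paste(bad, collapse = ", "))
  structure(list(intercept = intercept, coef = coef), class = "risk_equation")
}

## covariate design matrix for a cohort (columns follow risk_equation names)
risk_covariates <- function(cohort) {
  cbind(age = cohort$age - 60,
        male = as.numeric(cohort$sex == "male"),
        `race_NH-Black` = as.numeric(cohort$race_ethnicity == "NH-Black"),
        race_Hispanic = as.numeric(cohort$race_ethnicity == "Hispanic"),
        race_Other = as.numeric(cohort$race_ethnicity == "Other"),
        bmi = cohort$bmi - 30,
        hba1c = cohort$hba1c - 7,
        hypertension = as.numeric(cohort$hypertension),
        cvd_history = as.numeric(cohort$cvd_history))
}

#' Annual transition probability for individuals
#'
#' Inverse-logit of the equation's linear predictor evaluated on each row of
#' the cohort. Deterministic.
#'
#' @param cohort cohort `data.frame` (one or more rows).
#' @param eq a [risk_equation()].
#' @return Numeric vector of probabilities in \[0, 1\], one per row.
#' @export
annual_probability <- function(cohort, eq) {
  stopifnot(inherits(eq, "risk_equation"))
  X <- risk_covariates(cohort)
  lp <- rep(eq$intercept, nrow(cohort))
  for (nm in names(eq$coef)) {
    if (!nm %in% colnames(X)) stop("configuration error: no covariate '", nm, "'")
    lp <- lp + eq$coef[[nm]] * X[, nm]
  }
  unname(stats::plogis(lp))
}

#' Relative risk from a change in fruit and vegetable intake
#'
#' Log-linear dose-response: `RR = exp(attenuation * delta * log(rr_per_serving))`.
#' `attenuation` in (0, 1\] scales the log relative risk toward the null at
#' older ages (proportional attenuation).
#'
#' @param delta_servings change in daily servings (policy minus status quo).
#' @param rr_per_serving relative risk per +1 serving/day (< 1 protective).
#' @param attenuation multiplicative log-RR scaling in (0, 1\].
#' @return Relative risk (> 0).
#' @export
rr_from_delta <- function(delta_servings, rr_per_serving, attenuation = 1) {
  if (any(rr_per_serving <= 0)) stop("rr_per_serving must be positive")
  if (any(attenuation <= 0 | attenuation > 1)) stop("attenuation must be in (0, 1]")
  exp(attenuation * delta_servings * log(rr_per_serving))
}

#' Apply a relative risk to an annual probability
#'
#' Rate-based adjustment `p' = 1 - (1 - p)^rr`: the annual probability is
#' converted to a cumulative hazard, scaled by the relative risk, and
#' converted back. Preserves `p' = p` at `rr = 1`, keeps `p'` in \[0, 1\],
#' and agrees with the naive multiplicative `p * rr` to first order as
#' `p -> 0`.
#'
#' @param p annual probability in \[0, 1\].
#' @param rr relative risk (> 0).
#' @return Adjusted probability.
#' @export
adjust_probability <- function(p, rr) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  if (any(rr <= 0)) stop("rr must be positive")
  1 - (1 - p)^rr
}

#' Age-band attenuation factor for the diet-disease pathway
#'
#' @param age numeric vector of ages.
#' @param schedule named vector of attenuation factors by age band lower
#'   bound (e.g. `c("40" = 1, "60" = 0.8, "70" = 0.6, "80" = 0.4)`).
#' @return Attenuation factor per individual.
#' @export
age_attenuation <- function(age, schedule) {
  cuts <- as.numeric(names(schedule))
  unname(schedule[findInterval(age, cuts)])
}

#' Default risk configuration
#'
#' Bundles the five transition equations, the diet-disease relative risks
#' (CHD 0.95 and stroke 0.96 per +1 serving/day of fruits and vegetables,
#' attenuating with age), the first-event CHD/stroke handling, and a
#' synthetic age-sex life table for non-CVD mortality (Gompertz-shaped,
#' doubling roughly every 8 years, female rates 25% lower). All values are
#' synthetic defaults exposed for user override.
#'
#' @return A list with elements `equations`, `diet_rr`, `mortality`.
#' @export
default_risk_config <- function() {
  list(
    equations = list(
      first_chd = risk_equation(
        intercept = stats::qlogis(0.012),
        coef = c(age = 0.06, male = 0.30, bmi = 0.02, hba1c = 0.10,
                 hypertension = 0.35, `race_NH-Black` = 0.15,
                 race_Hispanic = 0.05)),
      first_stroke = risk_equation(
        intercept = stats::qlogis(0.008),
        coef = c(age = 0.07, male = 0.15, bmi = 0.015, hba1c = 0.08,
                 hypertension = 0.50, `race_NH-Black` = 0.25,
                 race_Hispanic = 0.05)),
      recurrent_cvd = risk_equation(
        intercept = stats::qlogis(0.045),
        coef = c(age = 0.05, male = 0.15, bmi = 0.015, hba1c = 0.08,
                 hypertension = 0.25)),
      cvd_death = risk_equation(
        intercept = stats::qlogis(0.012),
        coef = c(age = 0.08, male = 0.20, hba1c = 0.05))),
    diet_rr = list(
      rr_chd_per_serving = 0.95,
      rr_stroke_per_serving = 0.96,
      attenuation_schedule = c("40" = 1.0, "60" = 0.8, "70" = 0.6, "80" = 0.4)),
    mortality = list(
      ## log annual non-CVD death probability = a + b * age, female x 0.75
      gompertz_a = log(0.010) - (log(2) / 8) * 60,
      gompertz_b = log(2) / 8,
      female_factor = 0.75,
      cap = 0.7))
}

#' Annual non-CVD mortality probability
#'
#' @param age,sex vectors of age (years) and sex labels.
#' @param mortality mortality block of [default_risk_config()].
#' @return Annual probability of death from non-CVD causes.
#' @export
non_cvd_mortality <- function(age, sex, mortality = default_risk_config()$mortality) {
  p <- exp(mortality$gompertz_a + mortality$gompertz_b * age)
  p <- p * ifelse(sex == "female", mortality$female_factor, 1)
  pmin(p, mortality$cap)
}

#' Trajectory rules for annual risk-factor updates
#'
#' Secular drift terms (per-year additive changes applied to everyone) plus
#' the intervention level shifts applied while enrolled. Defaults: no secular
#' drift.
#'
#' @param drift named numeric vector of per-year additive drifts on `bmi`,
#'   `hba1c`, `fv_servings`.
#' @return An object of class `trajectory_rules`.
#' @export
trajectory_rules <- function(drift = c(bmi = 0, hba1c = 0, fv_servings = 0)) {
  structure(list(drift = drift), class = "trajectory_rules")
}

#' Annual risk-factor update
#'
#' Advances a cohort one simulation year: age increments by 1, secular drifts
#' accumulate, and the intervention deltas (change in fruit and vegetable
#' servings, BMI, HbA1c) are applied as level shifts that hold while enrolled
#' and are removed entirely on exit (benefits cease on disenrollment).
#' Risk-factor state is reconstructed each year from the baseline columns
#' (`bmi`, `hba1c`, `fruit_servings`, `veg_servings` are treated as
#' baseline), so a year of enrollment leaves no residue after exit.
#'
#' @param cohort cohort `data.frame` with baseline risk factors.
#' @param year_index simulation year (1-based).
#' @param rules a [trajectory_rules()].
#' @param enrolled logical vector (recycled): enrolled this year?
#' @param effects an [intervention_effects()] object, or `NULL` for none.
#' @param deltas optional named list/vector overriding the effect means
#'   (`fv_servings`, `bmi`, `hba1c`) — used by PSA draws and percentile sweeps.
#' @return The cohort with columns `age`, `bmi`, `hba1c`, `fv_total` set to
#'   their year-`year_index` values (baseline columns untouched except age).
#' @export
update_risk_factors <- function(cohort, year_index, rules = trajectory_rules(),
                                enrolled = TRUE, effects = NULL, deltas = NULL) {
  stopifnot(year_index >= 1)
  d <- c(fv_servings = 0, bmi = 0, hba1c = 0)
  if (!is.null(deltas)) {
    d[names(deltas)] <- unlist(deltas)
  } else if (!is.null(effects)) {
    d <- c(fv_servings = effects$effects$fv_servings$mean,
           bmi = effects$effects$bmi$mean,
           hba1c = effects$effects$hba1c$mean)
  }
  enr <- as.numeric(rep_len(enrolled, nrow(cohort)))
  out <- cohort
  out$age <- cohort$age + year_index
  out$bmi <- cohort$bmi + rules$drift[["bmi"]] * year_index + enr * d[["bmi"]]
  out$hba1c <- cohort$hba1c + rules$drift[["hba1c"]] * year_index +
    enr * d[["hba1c"]]
  out$fv_total <- cohort$fruit_servings + cohort$veg_servings +
    rules$drift[["fv_servings"]] * year_index + enr * d[["fv_servings"]]
  out
}
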