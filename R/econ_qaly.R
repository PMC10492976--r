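#' Program cost parameters
#'
#' Intervention cost structure of a national produce prescription program:
#' fruits and vegetables offered at $42/person/month, of which $32/month is
#' actually redeemed (cost accrual uses the redeemed value; the offered value
#' is retained for reporting); administration at 15% of total program cost in
#' steady state (alternative presets: 8%, SNAP-like; 21.3%, WIC-like), with a
#' first-year launch premium in which administration equals 50% of food cost
#' (one third of total program cost). Acute-event and productivity unit costs
#' are synthetic configuration scalars; all monetary values are 2021 USD.
#'
#' @param monthly_offered $/person/month offered.
#' @param monthly_redeemed $/person/month redeemed (accrued as food cost).
#' @param admin_share_steady steady-state administrative share of total
#'   program cost, in (0, 1).
#' @param acute_cost_chd,acute_cost_stroke $ per acute event.
#' @param productivity_chd,productivity_stroke $ per prevalent case per year.
#' @param hba1c_cost_slope $ per year per HbA1c point above `hba1c_cost_ref`,
#'   entering only the non-CVD diabetes cost component.
#' @param hba1c_cost_ref HbA1c reference point (%).
#' @param discount_rate annual discount rate for costs and QALYs.
#' @return An object of class `cost_params`.
#' @export
cost_params <- function(monthly_offered = 42, monthly_redeemed = 32,
                        admin_share_steady = 0.15,
                        acute_cost_chd = 20000, acute_cost_stroke = 16000,
                        productivity_chd = 1700, productivity_stroke = 1250,
                        hba1c_cost_slope = 1000, hba1c_cost_ref = 7,
                        discount_rate = 0.03) {
  stopifnot(monthly_offered >= 0, monthly_redeemed >= 0,
            admin_share_steady > 0, admin_share_steady < 1,
            acute_cost_chd >= 0, acute_cost_stroke >= 0,
            productivity_chd >= 0, productivity_stroke >= 0,
            hba1c_cost_slope >= 0)
  structure(list(monthly_offered = monthly_offered,
                 monthly_redeemed = monthly_redeemed,
                 admin_share_steady = admin_share_steady,
                 acute_cost_chd = acute_cost_chd,
                 acute_cost_stroke = acute_cost_stroke,
                 productivity_chd = productivity_chd,
                 productivity_stroke = productivity_stroke,
                 hba1c_cost_slope = hba1c_cost_slope,
                 hba1c_cost_ref = hba1c_cost_ref,
                 discount_rate = discount_rate,
                 currency_year = 2021),
            class = "cost_params")
}

#' Per-person intervention cost by program year
#'
#' Food cost is 12 x the monthly redeemed value. Administration equals 50% of
#' food cost in program year 1 (launch premium: one third of total program
#' cost) and `food * s / (1 - s)` thereafter, so that
#' `admin / (admin + food) = s`, the steady-state administrative share.
#'
#' @param year_index program year (1-based).
#' @param params a [cost_params()].
#' @return Named list with `food_cost` and `admin_cost` ($/person-year).
#' @export
intervention_cost <- function(year_index, params = cost_params()) {
  stopifnot(year_index >= 1)
  food <- 12 * params$monthly_redeemed
  s <- params$admin_share_steady
  admin <- if (year_index == 1) 0.5 * food else food * s / (1 - s)
  list(food_cost = food, admin_cost = admin)
}

#' Health-care cost prediction coefficients
#'
#' Linear annual-cost model over the covariates the simulation tracks: age,
#' sex, race or ethnicity, BMI, diabetes, hypertension, and CVD history,
#' plus an HbA1c-dependent diabetes-control term that enters only the
#' non-CVD component of diabetes cost (this is the guard against
#' double-counting CVD benefits: averted CVD events already remove the
#' CVD-dependent costs, so better glycemic control is credited only with the
#' CVD-independent share). The default coefficients are synthetic stand-ins
#' on a plausible US scale (2021 USD), shipped as configuration.
#'
#' @param intercept baseline annual cost for the reference individual.
#' @param coef named numeric vector; recognized names are `age` (per year
#'   over 60), `male`, `race_NH-Black`, `race_Hispanic`, `race_Other`,
#'   `bmi` (per kg/m² over 30), `diabetes`, `hypertension`, `cvd_history`.
#' @return An object of class `healthcare_cost_model`.
#' @export
healthcare_cost_model <- function(
    intercept = 6000,
    coef = c(age = 120, male = -300, `race_NH-Black` = 200,
             race_Hispanic = -150, race_Other = 0, bmi = 90,
             diabetes = 3500, hypertension = 1200, cvd_history = 6500)) {
  structure(list(intercept = intercept, coef = coef),
            class = "healthcare_cost_model")
}

#' Predicted annual health-care cost per individual
#'
#' @param cohort cohort `data.frame`; uses current `bmi`/`hba1c` columns, so
#'   it may be a risk-factor-updated cohort.
#' @param model a [healthcare_cost_model()].
#' @param params a [cost_params()] (supplies the HbA1c slope and reference).
#' @return Nonnegative $/year per row.
#' @export
annual_healthcare_cost <- function(cohort, model = healthcare_cost_model(),
                                   params = cost_params()) {
  X <- cbind(age = cohort$age - 60,
             male = as.numeric(cohort$sex == "male"),
             `race_NH-Black` = as.numeric(cohort$race_ethnicity == "NH-Black"),
             race_Hispanic = as.numeric(cohort$race_ethnicity == "Hispanic"),
             race_Other = as.numeric(cohort$race_ethnicity == "Other"),
             bmi = cohort$bmi - 30,
             diabetes = as.numeric(cohort$diabetes),
             hypertension = as.numeric(cohort$hypertension),
             cvd_history = as.numeric(cohort$cvd_history))
  cost <- rep(model$intercept, nrow(cohort))
  for (nm in names(model$coef)) {
    if (!nm %in% colnames(X)) stop("configuration error: no covariate '", nm, "'")
    cost <- cost + model$coef[[nm]] * X[, nm]
  }
  ## diabetes-control term: non-CVD diabetes cost only
  cost <- cost + as.numeric(cohort$diabetes) * params$hba1c_cost_slope *
    pmax(0, cohort$hba1c - params$hba1c_cost_ref)
  unname(pmax(cost, 0))
}

#' EQ-5D utility prediction parameters
#'
#' Linear prediction of health-related quality of life on the 0.00 (death) to
#' 1.00 (perfect health) scale from demographics, socioeconomics and chronic
#' conditions, with one-year decrements for acute events: −0.055 for acute
#' CHD and −0.3 for acute stroke in the event year only. Predictions are
#' clamped to \[0, 1\]. Default coefficients are synthetic stand-ins.
#'
#' @param intercept utility of the reference individual.
#' @param coef named numeric vector; recognized names are `age` (per year
#'   over 60), `male`, `bmi` (per kg/m² over 30), `diabetes`, `hypertension`,
#'   `cvd_history`, `income_low` (income-poverty ratio below 1.30).
#' @param decrement_chd,decrement_stroke event-year utility decrements.
#' @return An object of class `utility_params`.
#' @export
utility_params <- function(
    intercept = 0.86,
    coef = c(age = -0.0025, male = 0.01, bmi = -0.003, diabetes = -0.04,
             hypertension = -0.02, cvd_history = -0.06, income_low = -0.03),
    decrement_chd = 0.055, decrement_stroke = 0.3) {
  structure(list(intercept = intercept, coef = coef,
                 decrement_chd = decrement_chd,
                 decrement_stroke = decrement_stroke),
            class = "utility_params")
}

#' Annual utility with acute-event decrements
#'
#' @param cohort cohort `data.frame` (current risk factors).
#' @param acute_chd,acute_stroke logical vectors (recycled): acute event this
#'   year?
#' @param params a [utility_params()].
#' @return Utility in \[0, 1\] per row.
#' @export
annual_utility <- function(cohort, acute_chd = FALSE, acute_stroke = FALSE,
                           params = utility_params()) {
  X <- cbind(age = cohort$age - 60,
             male = as.numeric(cohort$sex == "male"),
             bmi = cohort$bmi - 30,
             diabetes = as.numeric(cohort$diabetes),
             hypertension = as.numeric(cohort$hypertension),
             cvd_history = as.numeric(cohort$cvd_history),
             income_low = as.numeric(cohort$income_poverty_ratio == "<1.30"))
  u <- rep(params$intercept, nrow(cohort))
  for (nm in names(params$coef)) {
    if (!nm %in% colnames(X)) stop("configuration error: no covariate '", nm, "'")
    u <- u + params$coef[[nm]] * X[, nm]
  }
  u <- pmin(pmax(u, 0), 1)  # prediction clamped before decrements
  u <- u - params$decrement_chd * as.numeric(rep_len(acute_chd, nrow(cohort))) -
    params$decrement_stroke * as.numeric(rep_len(acute_stroke, nrow(cohort)))
  unname(pmin(pmax(u, 0), 1))
}

#' Annual productivity cost of prevalent CVD
#'
#' Per-prevalent-case annual productivity losses: `productivity_chd` for each
#' individual with prevalent coronary heart disease and `productivity_stroke`
#' for each with prevalent stroke (additive if both).
#'
#' @param prevalent_chd,prevalent_stroke logical vectors.
#' @param params a [cost_params()].
#' @return $/year per individual.
#' @export
productivity_cost <- function(prevalent_chd, prevalent_stroke,
                              params = cost_params()) {
  params$productivity_chd * as.numeric(prevalent_chd) +
    params$productivity_stroke * as.numeric(prevalent_stroke)
}

#' Present value of an amount accrued in a given year
#'
#' Annual discounting with the first year undiscounted:
#' `amount / (1 + rate)^(year_index - 1)`.
#'
#' @param amount numeric amount ($ or QALYs).
#' @param year_index year of accrual (1-based).
#' @param rate annual discount rate (>= 0).
#' @return Present value.
#' @export
discount <- function(amount, year_index, rate = 0.03) {
  if (rate < 0) stop("discount rate must be nonnegative")
  stopifnot(all(year_index >= 1))
  amount / (1 + rate)^(year_index - 1)
}
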