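#' Paired policy-versus-status-quo microsimulation
#'
#' Runs the annual-cycle state-transition microsimulation twice on the same
#' cohort — once with the produce prescription in place, once under the
#' status quo — using common random numbers: every person, cycle and draw
#' purpose (first CHD, first stroke, recurrent CVD, CVD death, non-CVD
#' death) consumes the same uniform variate in both arms, so incremental
#' differences reflect the intervention alone. Individuals are followed
#' until death or `max_cycles` annual cycles (default 60), whichever comes
#' first.
#'
#' Within a cycle the ordering is: risk-factor update, event draws,
#' mortality draws, accrual. Death precludes subsequent events in the same
#' cycle; the death year itself accrues its costs and utility, and all later
#' years accrue nothing. Participation below 1 is resolved by a seeded
#' Bernoulli draw at baseline and fixed thereafter; non-participants receive
#' no effects and no intervention costs in the policy arm.
#'
#' @param cohort baseline cohort `data.frame` (see [generate_cohort()]).
#' @param effects an [intervention_effects()] object.
#' @param risk_cfg risk configuration ([default_risk_config()]).
#' @param cost_pars a [cost_params()].
#' @param hc_model a [healthcare_cost_model()].
#' @param util_pars a [utility_params()].
#' @param rules a [trajectory_rules()].
#' @param scenario list with `participation_fraction` (default 1),
#'   `max_cycles` (default 60), `chd_share` (fraction of recurrent events
#'   treated as CHD-type, default 0.6).
#' @param seed integer seed driving all simulation randomness.
#' @param deltas optional named vector (`fv_servings`, `bmi`, `hba1c`)
#'   overriding the effect means (PSA draws, percentile sweeps).
#' @return An object of class `paired_sim`: list with the baseline `cohort`,
#'   the per-arm ledgers `policy` and `control` (each a list of n x T
#'   matrices: `alive`, `utility`, event indicators, cost components),
#'   `enrolled`, `max_cycles` and `seed`.
#' @export
run_paired <- function(cohort, effects = default_intervention_effects(),
                       risk_cfg = default_risk_config(),
                       cost_pars = cost_params(),
                       hc_model = healthcare_cost_model(),
                       util_pars = utility_params(),
                       rules = trajectory_rules(),
                       scenario = list(), seed = 1, deltas = NULL) {
  n <- nrow(cohort)
  part <- if (is.null(scenario$participation_fraction)) 1 else scenario$participation_fraction
  Tmax <- if (is.null(scenario$max_cycles)) 60 else scenario$max_cycles
  chd_share <- if (is.null(scenario$chd_share)) 0.6 else scenario$chd_share
  stopifnot(part >= 0, part <= 1, Tmax >= 1)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  enrolled <- stats::runif(n) < part
  ## common random numbers: one uniform per person, cycle and purpose
  U <- array(stats::runif(n * 5L * Tmax), dim = c(n, 5L, Tmax))

  if (is.null(deltas)) {
    deltas <- c(fv_servings = effects$effects$fv_servings$mean,
                bmi = effects$effects$bmi$mean,
                hba1c = effects$effects$hba1c$mean)
  }
  zero <- c(fv_servings = 0, bmi = 0, hba1c = 0)

  policy <- sim_arm(cohort, enrolled, deltas, TRUE, risk_cfg, cost_pars,
                    hc_model, util_pars, rules, U, Tmax, chd_share)
  control <- sim_arm(cohort, rep(FALSE, n), zero, FALSE, risk_cfg, cost_pars,
                     hc_model, util_pars, rules, U, Tmax, chd_share)
  structure(list(cohort = cohort, policy = policy, control = control,
                 enrolled = enrolled, max_cycles = Tmax, seed = seed),
            class = "paired_sim")
}

## one simulation arm; U is the shared uniform array
sim_arm <- function(cohort, enrolled, deltas, is_policy, risk_cfg, cost_pars,
                    hc_model, util_pars, rules, U, Tmax, chd_share) {
  n <- nrow(cohort)
  eqs <- risk_cfg$equations
  dr <- risk_cfg$diet_rr

  alive <- rep(TRUE, n)
  cvd_hist <- cohort$cvd_history
  prev_chd <- cohort$angina | cohort$chd | cohort$mi
  prev_stroke <- cohort$stroke

  mk <- function() matrix(0, n, Tmax)
  mkl <- function() matrix(FALSE, n, Tmax)
  led <- list(alive = mkl(), utility = mk(),
              first_chd = mkl(), first_stroke = mkl(), recurrent = mkl(),
              cvd_death = mkl(), other_death = mkl(),
              cost_int_food = mk(), cost_int_admin = mk(),
              cost_healthcare = mk(), cost_acute = mk(),
              cost_productivity = mk())

  for (t in seq_len(Tmax)) {
    if (!any(alive)) break
    cur <- update_risk_factors(cohort, t, rules, enrolled, deltas = deltas)
    cur$cvd_history <- cvd_hist
    att <- age_attenuation(cur$age, dr$attenuation_schedule)
    dfv <- as.numeric(enrolled) * deltas[["fv_servings"]]
    rr_chd <- rr_from_delta(dfv, dr$rr_chd_per_serving, att)
    rr_str <- rr_from_delta(dfv, dr$rr_stroke_per_serving, att)

    p_fchd <- adjust_probability(annual_probability(cur, eqs$first_chd), rr_chd)
    p_fstr <- adjust_probability(annual_probability(cur, eqs$first_stroke), rr_str)
    p_rec <- adjust_probability(annual_probability(cur, eqs$recurrent_cvd), rr_chd)
    p_cvdd <- annual_probability(cur, eqs$cvd_death)
    p_oth <- non_cvd_mortality(cur$age, cur$sex, risk_cfg$mortality)

    u1 <- U[, 1, t]; u2 <- U[, 2, t]; u3 <- U[, 3, t]
    u4 <- U[, 4, t]; u5 <- U[, 5, t]

    e_fchd <- alive & !cvd_hist & (u1 < p_fchd)
    e_fstr <- alive & !cvd_hist & !e_fchd & (u2 < p_fstr)
    e_rec <- alive & cvd_hist & (u3 < p_rec)
    ## conditional on a recurrent event, u3/p_rec is uniform: reuse it for
    ## the CHD/stroke type split so the type is shared across arms
    rec_chd <- e_rec & (u3 < p_rec * chd_share)
    rec_str <- e_rec & !rec_chd
    had_cvd <- cvd_hist | e_fchd | e_fstr
    e_cvdd <- alive & had_cvd & (u4 < p_cvdd)
    e_othd <- alive & !e_cvdd & (u5 < p_oth)

    acute_chd <- e_fchd | rec_chd
    acute_str <- e_fstr | rec_str

    ic <- intervention_cost(t, cost_pars)
    a <- as.numeric(alive)
    enr_a <- as.numeric(alive & enrolled)
    led$cost_int_food[, t] <- enr_a * ic$food_cost
    led$cost_int_admin[, t] <- enr_a * ic$admin_cost
    led$cost_healthcare[, t] <- a * annual_healthcare_cost(cur, hc_model, cost_pars)
    led$cost_acute[, t] <- a * (cost_pars$acute_cost_chd * acute_chd +
                                  cost_pars$acute_cost_stroke * acute_str)
    led$cost_productivity[, t] <-
      a * productivity_cost(prev_chd, prev_stroke, cost_pars)
    led$utility[, t] <- a * annual_utility(cur, acute_chd, acute_str, util_pars)
    led$alive[, t] <- alive
    led$first_chd[, t] <- e_fchd
    led$first_stroke[, t] <- e_fstr
    led$recurrent[, t] <- e_rec
    led$cvd_death[, t] <- e_cvdd
    led$other_death[, t] <- e_othd

    cvd_hist <- cvd_hist | e_fchd | e_fstr
    prev_chd <- prev_chd | e_fchd | rec_chd
    prev_stroke <- prev_stroke | e_fstr | rec_str
    alive <- alive & !e_cvdd & !e_othd
  }
  led
}

#' Aggregate a paired simulation to incremental population totals
#'
#' Survey-weight-scaled, discounted incremental totals of the policy arm
#' over the status quo at a given horizon: CVD events averted (first,
#' recurrent, total), QALYs gained, cost changes by category, net costs by
#' perspective, and rates per 100,000 patients.
#'
#' @param sim a `paired_sim` from [run_paired()].
#' @param horizon number of years to aggregate (`"lifetime"` = all simulated
#'   cycles; 5 and 10 are the short horizons).
#' @param discount_rate annual discount rate applied to costs and QALYs.
#' @return A list of incremental quantities, including the per-person
#'   discounted incremental contributions (`per_person`) used for
#'   sampling-variance estimation.
#' @export
aggregate_paired <- function(sim, horizon = "lifetime", discount_rate = 0.03) {
  stopifnot(inherits(sim, "paired_sim"))
  h <- if (identical(horizon, "lifetime")) sim$max_cycles else as.integer(horizon)
  if (h > sim$max_cycles) stop("horizon exceeds simulated cycles (", sim$max_cycles, ")")
  yrs <- seq_len(h)
  w <- sim$cohort$survey_weight
  dfac <- 1 / (1 + discount_rate)^(yrs - 1)

  tot <- function(led, fld, disc = TRUE) {
    m <- led[[fld]][, yrs, drop = FALSE]
    if (disc) as.vector(m %*% dfac) else rowSums(m)  # per person
  }
  ev <- function(led, fld) rowSums(led[[fld]][, yrs, drop = FALSE])

  per <- list(
    first = ev(sim$control, "first_chd") + ev(sim$control, "first_stroke") -
      ev(sim$policy, "first_chd") - ev(sim$policy, "first_stroke"),
    recurrent = ev(sim$control, "recurrent") - ev(sim$policy, "recurrent"),
    qaly = tot(sim$policy, "utility") - tot(sim$control, "utility"),
    int_food = tot(sim$policy, "cost_int_food"),
    int_admin = tot(sim$policy, "cost_int_admin"),
    hc_save = tot(sim$control, "cost_healthcare") + tot(sim$control, "cost_acute") -
      tot(sim$policy, "cost_healthcare") - tot(sim$policy, "cost_acute"),
    prod_save = tot(sim$control, "cost_productivity") -
      tot(sim$policy, "cost_productivity"))
  per$total <- per$first + per$recurrent

  W <- sum(w)
  agg <- lapply(per, function(d) sum(w * d))
  out <- list(
    horizon = horizon,
    n_persons = nrow(sim$cohort),
    population = W,
    first_cvd_averted = agg$first,
    recurrent_cvd_averted = agg$recurrent,
    total_cvd_averted = agg$total,
    qalys_gained = agg$qaly,
    intervention_food_cost = agg$int_food,
    intervention_admin_cost = agg$int_admin,
    intervention_cost_total = agg$int_food + agg$int_admin,
    healthcare_savings = agg$hc_save,
    productivity_savings = agg$prod_save,
    per_person = per,
    weights = w,
    discount_rate = discount_rate)
  out$net_cost_healthcare <- out$intervention_cost_total - out$healthcare_savings
  out$net_cost_societal <- out$net_cost_healthcare - out$productivity_savings
  out$cvd_averted_per_100k <- 1e5 * agg$total / W
  out$icer_healthcare <- icer(out$net_cost_healthcare, out$qalys_gained)
  out$icer_societal <- icer(out$net_cost_societal, out$qalys_gained)
  out
}

#' Subgroup aggregation of a paired simulation
#'
#' Stratifies the cohort by a baseline field and aggregates each stratum
#' separately. Strata partition the cohort, so stratum totals sum to the
#' overall totals.
#'
#' @param sim a `paired_sim`.
#' @param stratifier name of a baseline cohort column (e.g. `"sex"`,
#'   `"insurance"`, `"race_ethnicity"`, `"education"`).
#' @param horizon,discount_rate as in [aggregate_paired()].
#' @return A `data.frame`, one row per stratum, with the incremental totals
#'   and per-100,000 rates.
#' @export
subgroup_aggregate <- function(sim, stratifier, horizon = "lifetime",
                               discount_rate = 0.03) {
  if (!stratifier %in% names(sim$cohort)) {
    stop("unknown stratifier: ", stratifier)
  }
  overall <- aggregate_paired(sim, horizon, discount_rate)
  g <- sim$cohort[[stratifier]]
  w <- sim$cohort$survey_weight
  per <- overall$per_person
  rows <- lapply(sort(unique(as.character(g))), function(lv) {
    i <- g == lv
    data.frame(
      stratum = lv,
      population = sum(w[i]),
      first_cvd_averted = sum(w[i] * per$first[i]),
      recurrent_cvd_averted = sum(w[i] * per$recurrent[i]),
      total_cvd_averted = sum(w[i] * per$total[i]),
      qalys_gained = sum(w[i] * per$qaly[i]),
      intervention_cost_total = sum(w[i] * (per$int_food[i] + per$int_admin[i])),
      healthcare_savings = sum(w[i] * per$hc_save[i]),
      productivity_savings = sum(w[i] * per$prod_save[i]),
      cvd_averted_per_100k = 1e5 * sum(w[i] * per$total[i]) / sum(w[i]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$net_cost_healthcare <- out$intervention_cost_total - out$healthcare_savings
  out$net_cost_societal <- out$net_cost_healthcare - out$productivity_savings
  out
}

#' Ledger as a long-format data frame
#'
#' Flattens one arm of a paired simulation into the long person-year format
#' (one row per person per simulated year) for CSV export.
#'
#' @param sim a `paired_sim`.
#' @param arm `"policy"` or `"control"`.
#' @return A `data.frame` with person, year, arm, alive flag, event flags,
#'   cost components and utility.
#' @export
ledger_df <- function(sim, arm = c("policy", "control")) {
  arm <- match.arg(arm)
  led <- sim[[arm]]
  n <- nrow(sim$cohort); Tmax <- sim$max_cycles
  data.frame(
    person_id = rep(sim$cohort$person_id, Tmax),
    year = rep(seq_len(Tmax), each = n),
    arm = arm,
    alive = as.vector(led$alive),
    enrolled = rep(if (arm == "policy") sim$enrolled else FALSE, Tmax),
    first_chd = as.vector(led$first_chd),
    first_stroke = as.vector(led$first_stroke),
    recurrent_cvd = as.vector(led$recurrent),
    cvd_death = as.vector(led$cvd_death),
    other_death = as.vector(led$other_death),
    cost_intervention_food = as.vector(led$cost_int_food),
    cost_intervention_admin = as.vector(led$cost_int_admin),
    cost_healthcare = as.vector(led$cost_healthcare),
    cost_acute_event = as.vector(led$cost_acute),
    cost_productivity = as.vector(led$cost_productivity),
    utility = as.vector(led$utility),
    stringsAsFactors = FALSE)
}
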