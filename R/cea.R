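#' Incremental cost-effectiveness ratio with dominance labels
#'
#' `net_cost / qalys_gained` when the ratio is informative; otherwise a
#' label: `"cost-saving"` when the intervention gains QALYs at negative net
#' cost, `"dominated"` when it loses QALYs at positive net cost,
#' `"undefined"` when no QALYs change.
#'
#' @param net_cost incremental net cost ($).
#' @param qalys_gained incremental QALYs.
#' @return A list with `value` ($/QALY, `NA` when labeled) and `label`
#'   (`"icer"`, `"cost-saving"`, `"dominated"`, or `"undefined"`).
#' @export
icer <- function(net_cost, qalys_gained) {
  if (qalys_gained == 0) return(list(value = NA_real_, label = "undefined"))
  if (qalys_gained > 0 && net_cost < 0) {
    return(list(value = NA_real_, label = "cost-saving"))
  }
  if (qalys_gained < 0 && net_cost > 0) {
    return(list(value = NA_real_, label = "dominated"))
  }
  list(value = net_cost / qalys_gained, label = "icer")
}

#' Rubin's rule for combining estimates across draws
#'
#' Combines point estimates and within-draw sampling variances over `m`
#' draws: total variance = mean within-draw variance + (1 + 1/m) x
#' between-draw variance; the 95% uncertainty interval is
#' mean ± 1.96 · sqrt(total variance).
#'
#' @param points numeric vector of per-draw point estimates (length >= 2).
#' @param within numeric vector of per-draw sampling variances.
#' @return List with `mean`, `total_variance`, `ui95`.
#' @export
rubins_combine <- function(points, within) {
  m <- length(points)
  if (m < 2) stop("Rubin's rule needs at least 2 draws")
  if (length(within) != m) stop("points and within-variances differ in length")
  qbar <- mean(points)
  W <- mean(within)
  B <- sum((points - qbar)^2) / (m - 1)
  total <- W + (1 + 1 / m) * B
  list(mean = qbar, total_variance = total,
       ui95 = c(qbar - 1.96 * sqrt(total), qbar + 1.96 * sqrt(total)))
}

## sampling variance of a survey-weighted total sum(w * d), treating the
## weighted contributions as iid (with-replacement approximation)
weighted_total_variance <- function(d, w) {
  z <- w * d
  n <- length(z)
  if (n < 2) return(0)
  n * stats::var(z)
}

#' Probabilistic sensitivity analysis parameter uncertainty
#'
#' Distributions for the uncertain inputs beyond the intervention effects:
#' diet-disease relative risks (lognormal on the log-RR), cost and utility
#' scale factors (normal multipliers truncated at 0). SDs are configuration.
#'
#' @param rr_log_sd SD of the log relative risks per serving.
#' @param cost_mult_sd SD of the multiplicative factor on intervention food
#'   cost (monthly redeemed value).
#' @param hc_mult_sd SD of the multiplicative factor on predicted health-care
#'   and acute-event costs.
#' @param util_dec_sd relative SD of the acute-event utility decrements.
#' @return A list of SDs used by [run_psa()].
#' @export
psa_config <- function(rr_log_sd = 0.01, cost_mult_sd = 0.10,
                       hc_mult_sd = 0.10, util_dec_sd = 0.20) {
  list(rr_log_sd = rr_log_sd, cost_mult_sd = cost_mult_sd,
       hc_mult_sd = hc_mult_sd, util_dec_sd = util_dec_sd)
}

#' Probabilistic sensitivity analysis
#'
#' Repeats the paired simulation `n_draws` times, each draw sampling every
#' uncertain parameter from its distribution (intervention effects from
#' their CI-derived normals; diet relative risks, cost and utility
#' parameters per [psa_config()]), and records the incremental outcomes at
#' the requested horizon. Parameter draws for draw `i` use substream seeds
#' derived from `base_seed + i`, so individual draws are independently
#' reproducible; the simulated event streams are common across draws (same
#' `base_seed`), so between-draw variation isolates parameter uncertainty
#' while cohort sampling noise is carried by the within-draw variance that
#' Rubin's rule combines with it.
#'
#' @param cohort baseline cohort.
#' @param effects an [intervention_effects()] object.
#' @param n_draws number of Monte Carlo draws (>= 2; 1000 in the full
#'   analysis).
#' @param base_seed integer seed.
#' @param horizon aggregation horizon (`"lifetime"`, 5 or 10).
#' @param risk_cfg,cost_pars,hc_model,util_pars,rules,scenario simulation
#'   configuration as in [run_paired()].
#' @param psa_cfg a [psa_config()].
#' @param discount_rate annual discount rate.
#' @return A list with `draws` (a `data.frame`, one row per draw:
#'   incremental events, QALYs, costs by perspective and their within-draw
#'   sampling variances) and `combined` (Rubin's-rule mean and 95%
#'   uncertainty interval per quantity).
#' @export
run_psa <- function(cohort, effects = default_intervention_effects(),
                    n_draws = 1000, base_seed = 1, horizon = "lifetime",
                    risk_cfg = default_risk_config(),
                    cost_pars = cost_params(),
                    hc_model = healthcare_cost_model(),
                    util_pars = utility_params(),
                    rules = trajectory_rules(),
                    scenario = list(), psa_cfg = psa_config(),
                    discount_rate = 0.03) {
  stopifnot(n_draws >= 2)
  rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    seed_i <- (as.integer(base_seed) + i) %% .Machine$integer.max
    eff_i <- effect_sampler(effects, 1, seed = seed_i)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed_i + 1L)
    rc <- risk_cfg
    rc$diet_rr$rr_chd_per_serving <-
      exp(stats::rnorm(1, log(risk_cfg$diet_rr$rr_chd_per_serving), psa_cfg$rr_log_sd))
    rc$diet_rr$rr_stroke_per_serving <-
      exp(stats::rnorm(1, log(risk_cfg$diet_rr$rr_stroke_per_serving), psa_cfg$rr_log_sd))
    cp <- cost_pars
    cp$monthly_redeemed <- cost_pars$monthly_redeemed *
      max(0, stats::rnorm(1, 1, psa_cfg$cost_mult_sd))
    hc_mult <- max(0, stats::rnorm(1, 1, psa_cfg$hc_mult_sd))
    cp$acute_cost_chd <- cost_pars$acute_cost_chd * hc_mult
    cp$acute_cost_stroke <- cost_pars$acute_cost_stroke * hc_mult
    hm <- hc_model
    hm$intercept <- hc_model$intercept * hc_mult
    hm$coef <- hc_model$coef * hc_mult
    up <- util_pars
    up$decrement_chd <- util_pars$decrement_chd *
      max(0, stats::rnorm(1, 1, psa_cfg$util_dec_sd))
    up$decrement_stroke <- util_pars$decrement_stroke *
      max(0, stats::rnorm(1, 1, psa_cfg$util_dec_sd))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())

    sim <- run_paired(cohort, effects, rc, cp, hm, up, rules, scenario,
                      seed = base_seed,
                      deltas = c(fv_servings = eff_i$fv_servings,
                                 bmi = eff_i$bmi, hba1c = eff_i$hba1c))
    ag <- aggregate_paired(sim, horizon, discount_rate)
    w <- ag$weights; per <- ag$per_person
    d_cost_hc <- per$int_food + per$int_admin - per$hc_save
    d_cost_soc <- d_cost_hc - per$prod_save
    rows[[i]] <- data.frame(
      draw = i,
      total_cvd_averted = ag$total_cvd_averted,
      first_cvd_averted = ag$first_cvd_averted,
      recurrent_cvd_averted = ag$recurrent_cvd_averted,
      qalys_gained = ag$qalys_gained,
      intervention_cost_total = ag$intervention_cost_total,
      healthcare_savings = ag$healthcare_savings,
      productivity_savings = ag$productivity_savings,
      net_cost_healthcare = ag$net_cost_healthcare,
      net_cost_societal = ag$net_cost_societal,
      var_qalys = weighted_total_variance(per$qaly, w),
      var_net_cost_healthcare = weighted_total_variance(d_cost_hc, w),
      var_net_cost_societal = weighted_total_variance(d_cost_soc, w),
      var_total_cvd_averted = weighted_total_variance(per$total, w))
  }
  draws <- do.call(rbind, rows)
  combined <- list(
    qalys_gained = rubins_combine(draws$qalys_gained, draws$var_qalys),
    net_cost_healthcare = rubins_combine(draws$net_cost_healthcare,
                                         draws$var_net_cost_healthcare),
    net_cost_societal = rubins_combine(draws$net_cost_societal,
                                       draws$var_net_cost_societal),
    total_cvd_averted = rubins_combine(draws$total_cvd_averted,
                                       draws$var_total_cvd_averted))
  ## ratio-of-means ICER across draws
  combined$icer_healthcare <- icer(mean(draws$net_cost_healthcare),
                                   mean(draws$qalys_gained))
  combined$icer_societal <- icer(mean(draws$net_cost_societal),
                                 mean(draws$qalys_gained))
  list(draws = draws, combined = combined, horizon = horizon,
       base_seed = base_seed)
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with positive net monetary benefit
#' `WTP x ΔQALY − Δcost` at each willingness-to-pay value.
#'
#' @param draws PSA draw `data.frame` (from `run_psa()$draws`).
#' @param wtp_grid willingness-to-pay values ($/QALY); the decision
#'   thresholds of interest are $50,000 and $150,000.
#' @param perspective `"healthcare"` or `"societal"`.
#' @return `data.frame` with `wtp` and `p_cost_effective`.
#' @export
ceac <- function(draws, wtp_grid = c(50000, 150000),
                 perspective = c("healthcare", "societal")) {
  perspective <- match.arg(perspective)
  if (nrow(draws) == 0) stop("no PSA draws")
  dc <- draws[[paste0("net_cost_", perspective)]]
  dq <- draws$qalys_gained
  p <- vapply(wtp_grid, function(wtp) mean(wtp * dq - dc > 0), numeric(1))
  data.frame(wtp = wtp_grid, p_cost_effective = p)
}

#' One-way sensitivity sweep over effect-size percentiles
#'
#' Reruns the paired simulation deterministically with all three
#' intervention effects moved jointly to the same percentile of their
#' uncertainty distributions. Percentiles are on the *benefit* scale: the
#' 2.5th percentile is the least favorable effect triple (the CI bounds
#' nearest the null: +0.45 servings/day, −0.16 kg/m², −0.28 points), the
#' 97.5th the most favorable. Under protective effects the ICER is
#' non-increasing in the percentile.
#'
#' @param cohort baseline cohort.
#' @param effects an [intervention_effects()] object.
#' @param percentiles percentiles in (0, 1) (default the reported seven).
#' @param horizon,discount_rate aggregation settings.
#' @param risk_cfg,cost_pars,hc_model,util_pars,rules,scenario,seed as in
#'   [run_paired()]; the same `seed` (hence the same random streams) is used
#'   at every percentile.
#' @return `data.frame`, one row per percentile: the effect triple, net
#'   costs, QALYs gained, ICER value and label per perspective.
#' @export
one_way_sweep <- function(cohort, effects = default_intervention_effects(),
                          percentiles = c(0.025, 0.10, 0.25, 0.50, 0.75, 0.90, 0.975),
                          horizon = "lifetime", discount_rate = 0.03,
                          risk_cfg = default_risk_config(),
                          cost_pars = cost_params(),
                          hc_model = healthcare_cost_model(),
                          util_pars = utility_params(),
                          rules = trajectory_rules(),
                          scenario = list(), seed = 1) {
  if (any(percentiles <= 0 | percentiles >= 1)) stop("percentiles must be in (0, 1)")
  rows <- lapply(percentiles, function(p) {
    ## benefit-scale percentile: favorable direction is + for F&V, - for
    ## BMI and HbA1c
    d <- c(fv_servings = effect_percentile(effects, "fv_servings", p),
           bmi = effect_percentile(effects, "bmi", 1 - p),
           hba1c = effect_percentile(effects, "hba1c", 1 - p))
    sim <- run_paired(cohort, effects, risk_cfg, cost_pars, hc_model,
                      util_pars, rules, scenario, seed = seed, deltas = d)
    ag <- aggregate_paired(sim, horizon, discount_rate)
    data.frame(percentile = p,
               delta_fv = d[["fv_servings"]], delta_bmi = d[["bmi"]],
               delta_hba1c = d[["hba1c"]],
               qalys_gained = ag$qalys_gained,
               net_cost_healthcare = ag$net_cost_healthcare,
               net_cost_societal = ag$net_cost_societal,
               icer_healthcare = ifelse(is.na(ag$icer_healthcare$value) &
                                          ag$icer_healthcare$label == "cost-saving",
                                        -Inf, ag$icer_healthcare$value),
               icer_healthcare_label = ag$icer_healthcare$label,
               icer_societal_label = ag$icer_societal$label)
  })
  do.call(rbind, rows)
}

#' Break-even monthly intervention cost (threshold analysis)
#'
#' Finds the maximum total monthly per-person intervention cost (redeemed
#' food plus administration) at which the program stays cost effective at
#' the willingness-to-pay threshold (default $150,000/QALY). Health outcomes
#' do not depend on program cost, so the simulation is frozen and only the
#' cost side is rescaled; the ICER is monotone non-decreasing in the monthly
#' cost and the break-even point is found by bisection to $0.10/month.
#'
#' @param sim a base-case `paired_sim` from [run_paired()].
#' @param cost_pars the [cost_params()] used for that run.
#' @param wtp willingness-to-pay threshold ($/QALY).
#' @param horizon,discount_rate aggregation settings.
#' @param perspective `"healthcare"` or `"societal"`.
#' @param tol bisection tolerance on the monthly cost ($).
#' @return List with `threshold_monthly` ($/person/month, `Inf` when no
#'   crossing below 10x the default), `default_monthly`, and the scale
#'   factor at the threshold.
#' @export
threshold_monthly_cost <- function(sim, cost_pars = cost_params(),
                                   wtp = 150000, horizon = "lifetime",
                                   discount_rate = 0.03,
                                   perspective = c("healthcare", "societal"),
                                   tol = 0.10) {
  perspective <- match.arg(perspective)
  ag <- aggregate_paired(sim, horizon, discount_rate)
  if (ag$qalys_gained <= 0) stop("threshold analysis needs positive QALYs gained")
  savings <- if (perspective == "healthcare") ag$healthcare_savings else
    ag$healthcare_savings + ag$productivity_savings
  C0 <- ag$intervention_cost_total  # scales linearly with monthly cost
  if (C0 <= 0) stop("base-case run has no intervention cost to rescale")
  s <- cost_pars$admin_share_steady
  default_monthly <- cost_pars$monthly_redeemed * (1 + s / (1 - s))
  icer_at <- function(f) (f * C0 - savings) / ag$qalys_gained
  lo <- 0; hi <- 10
  if (icer_at(hi) < wtp) {
    return(list(threshold_monthly = Inf, default_monthly = default_monthly,
                scale = Inf))
  }
  if (icer_at(lo) > wtp) {
    return(list(threshold_monthly = 0, default_monthly = default_monthly,
                scale = 0))
  }
  while ((hi - lo) * default_monthly > tol) {
    mid <- (lo + hi) / 2
    if (icer_at(mid) > wtp) hi <- mid else lo <- mid
  }
  f <- (lo + hi) / 2
  list(threshold_monthly = f * default_monthly,
       default_monthly = default_monthly, scale = f)
}

#' Table of incremental results across horizons
#'
#' Convenience report shaped like the headline results table: one row per
#' outcome, one column per horizon (5 years, 10 years, lifetime).
#'
#' @param sim a `paired_sim`.
#' @param horizons horizons to tabulate.
#' @param discount_rate annual discount rate.
#' @return A `data.frame` with an `outcome` column and one column per
#'   horizon.
#' @export
results_table <- function(sim, horizons = list(5, 10, "lifetime"),
                          discount_rate = 0.03) {
  cols <- lapply(horizons, function(h) {
    ag <- aggregate_paired(sim, h, discount_rate)
    c(total_cvd_events_averted = ag$total_cvd_averted,
      first_cvd_cases_averted = ag$first_cvd_averted,
      recurrent_cvd_events_averted = ag$recurrent_cvd_averted,
      qalys_gained = ag$qalys_gained,
      healthcare_cost_savings = ag$healthcare_savings,
      productivity_cost_savings = ag$productivity_savings,
      intervention_food_costs = ag$intervention_food_cost,
      intervention_admin_costs = ag$intervention_admin_cost,
      net_cost_healthcare = ag$net_cost_healthcare,
      net_cost_societal = ag$net_cost_societal,
      icer_healthcare = if (ag$icer_healthcare$label == "icer")
        ag$icer_healthcare$value else NA_real_,
      icer_societal = if (ag$icer_societal$label == "icer")
        ag$icer_societal$value else NA_real_)
  })
  out <- data.frame(outcome = names(cols[[1]]), stringsAsFactors = FALSE)
  for (i in seq_along(horizons)) {
    out[[paste0("horizon_", horizons[[i]])]] <- unname(cols[[i]])
  }
  out
}
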