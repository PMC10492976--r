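#' Full-run configuration bundle
#'
#' Collects every configurable block of the analysis — population preset,
#' intervention effects, risk equations, diet relative risks, cost and
#' utility parameters, scenario settings and CEA settings — into one list.
#' The default is the base case: full participation, lifetime horizon
#' (60 annual cycles), 3% discounting, 1000 PSA draws, willingness-to-pay
#' thresholds of $50,000 and $150,000 per QALY.
#'
#' @param participation_fraction fraction of eligible individuals enrolled.
#' @param admin_share_steady steady-state administrative share (presets:
#'   0.15 base case, 0.08 SNAP-like, 0.213 WIC-like).
#' @return A named list of configuration blocks.
#' @export
default_config <- function(participation_fraction = 1,
                           admin_share_steady = 0.15) {
  list(
    population = default_table1_spec(),
    effects = intervention_effects(participation_fraction = participation_fraction),
    risk = default_risk_config(),
    costs = cost_params(admin_share_steady = admin_share_steady),
    healthcare_model = healthcare_cost_model(),
    utilities = utility_params(),
    rules = trajectory_rules(),
    scenario = list(participation_fraction = participation_fraction,
                    max_cycles = 60, chd_share = 0.6),
    cea = list(wtp = c(50000, 150000), n_draws = 1000, discount_rate = 0.03,
               psa = psa_config()))
}

## strip S3 classes recursively so yaml can serialize the bundle
unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    attr(x, "insurance_raw") <- NULL
    lapply(x, unclass_deep)
  } else if (!is.matrix(x) && is.numeric(x) && !is.null(names(x))) {
    as.list(x)  # keep names: yaml drops them on atomic vectors
  } else if (is.matrix(x)) {
    list(.matrix = TRUE, dimnames = dimnames(x)[[1]], values = as.vector(x))
  } else x
}

#' Write / read a configuration bundle as YAML
#'
#' Serializes a [default_config()]-shaped bundle to YAML for inspection and
#' editing; `read_config` restores the S3 classes on the round trip.
#'
#' @param config a configuration bundle.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the configuration bundle.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  restore_matrix <- function(m) {
    k <- length(m$dimnames)
    matrix(unlist(m$values), k, k, dimnames = list(m$dimnames, m$dimnames))
  }
  to_vec <- function(x) unlist(x)
  pop <- raw$population
  spec <- population_spec(
    continuous = pop$continuous,
    categorical = lapply(pop$categorical, to_vec),
    correlation = restore_matrix(pop$correlation),
    binary = to_vec(pop$binary),
    cvd_subflags = to_vec(pop$cvd_subflags),
    cvd_age_slope = pop$cvd_age_slope,
    weight_meanlog = pop$weight_meanlog, weight_sdlog = pop$weight_sdlog,
    total_population = pop$total_population)
  eff <- raw$effects$effects
  effects <- intervention_effects(
    delta_fv = list(mean = eff$fv_servings$mean, ci95 = to_vec(eff$fv_servings$ci95)),
    delta_bmi = list(mean = eff$bmi$mean, ci95 = to_vec(eff$bmi$ci95)),
    delta_hba1c = list(mean = eff$hba1c$mean, ci95 = to_vec(eff$hba1c$ci95)),
    participation_fraction = raw$effects$participation_fraction)
  risk <- raw$risk
  risk$equations <- lapply(risk$equations, function(e) {
    risk_equation(e$intercept, to_vec(e$coef))
  })
  risk$diet_rr$attenuation_schedule <- to_vec(risk$diet_rr$attenuation_schedule)
  costs <- do.call(cost_params,
                   raw$costs[setdiff(names(raw$costs), "currency_year")])
  hc <- healthcare_cost_model(raw$healthcare_model$intercept,
                              to_vec(raw$healthcare_model$coef))
  ut <- utility_params(raw$utilities$intercept, to_vec(raw$utilities$coef),
                       raw$utilities$decrement_chd, raw$utilities$decrement_stroke)
  rules <- trajectory_rules(to_vec(raw$rules$drift))
  cea <- raw$cea
  cea$wtp <- to_vec(cea$wtp)
  list(population = spec, effects = effects, risk = risk, costs = costs,
       healthcare_model = hc, utilities = ut, rules = rules,
       scenario = raw$scenario, cea = cea)
}
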