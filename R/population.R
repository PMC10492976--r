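#' Population specification for the synthetic eligible cohort
#'
#' A `population_spec` is the distributional recipe the cohort generator
#' samples from: truncated-normal marginals for the continuous risk factors,
#' category probabilities for the categorical variables, a latent-Gaussian
#' correlation matrix linking the continuous variables, an age-dependent
#' logistic tilt for cardiovascular disease (CVD) history, and a lognormal
#' survey-weight model rescaled to a total represented population.
#'
#' @param continuous named list; each element a list with `mean`, `sd`
#'   (the target moments of the *realized* marginal), `lower`, `upper`
#'   (truncation bounds) and `family` (`"truncnorm"` or `"gamma"`). For
#'   `"truncnorm"` the underlying normal parameters are moment-matched at
#'   generation time so the truncated distribution has exactly the stated
#'   mean and SD; `"gamma"` (lower bound 0) accommodates the right-skewed
#'   diet variables whose SD exceeds what a lower-truncated normal can carry.
#' @param categorical named list; each element a named numeric vector of
#'   category probabilities summing to 1.
#' @param correlation correlation matrix over the continuous variables
#'   (dimnames must match `names(continuous)`); must be symmetric positive
#'   semi-definite.
#' @param binary named numeric vector of marginal probabilities for the
#'   binary variables (`hypertension`, `cvd_history`, `diabetes`,
#'   `food_insecure`).
#' @param cvd_subflags named numeric vector of *marginal* prevalences for the
#'   CVD-history sub-flags (`angina`, `chd`, `mi`, `stroke`).
#' @param cvd_age_slope log-odds increase in CVD-history probability per year
#'   of age; the intercept is calibrated at generation time so the marginal
#'   prevalence in `binary["cvd_history"]` holds.
#' @param weight_meanlog,weight_sdlog lognormal parameters for raw survey
#'   weights before rescaling.
#' @param total_population population total the survey weights sum to.
#'
#' @return An object of class `population_spec`.
#' @seealso [default_table1_spec()], [generate_cohort()]
#' @export
population_spec <- function(continuous, categorical, correlation, binary,
                            cvd_subflags, cvd_age_slope = 0.04,
                            weight_meanlog = 0, weight_sdlog = 0.5,
                            total_population = 6.5e6) {
  for (nm in names(categorical)) {
    p <- categorical[[nm]]
    if (abs(sum(p) - 1) > 1e-9) {
      stop("category probabilities for '", nm, "' must sum to 1 (got ",
           format(sum(p), digits = 12), ")")
    }
    if (any(p < 0)) stop("negative category probability in '", nm, "'")
  }
  for (nm in names(continuous)) {
    m <- continuous[[nm]]
    if (m$lower > m$upper) stop("truncation bounds for '", nm, "' are not ordered")
    if (m$sd < 0) stop("negative sd for '", nm, "'")
  }
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-10))) {
    stop("correlation matrix must be symmetric")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("correlation matrix for continuous variables is not positive ",
         "semi-definite (min eigenvalue ", format(min(ev), digits = 4), ")")
  }
  structure(
    list(continuous = continuous, categorical = categorical,
         correlation = correlation, binary = binary,
         cvd_subflags = cvd_subflags, cvd_age_slope = cvd_age_slope,
         weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
         total_population = total_population),
    class = "population_spec")
}

#' Default population preset: US adults 40-79 with diabetes and food insecurity
#'
#' Returns the [population_spec()] whose marginals equal the published
#' baseline characteristics of the eligible national sample (weighted means,
#' SDs and percentages): age mean 58.2 (SD 10.2) on 40-79, BMI 33.6 (7.95)
#' bounded below at 15, HbA1c 7.3 (1.95) bounded below at 4.5 — each a
#' truncated normal whose realized moments match the stated values — fruit
#' 0.86 (1.08) and vegetable 1.30 (1.04) servings/day as gamma, female 55.6%,
#' hypertension 74.8%, CVD history 30.0% with sub-flag prevalences
#' angina 15.8% / CHD 11.9% / MI 12.8% / stroke 9.1%, and diabetes and food
#' insecurity 100% (the eligibility criteria). The represented population
#' total is 6.5 million.
#'
#' The published insurance percentages (private 29.4, Medicare 26.9,
#' Medicaid 26.9, dual 12.5, none 16.5) describe overlapping coverage and sum
#' to 112.2; the generator needs a proper distribution, so they are
#' renormalized proportionally. The raw values are retained in the
#' `insurance_raw` attribute.
#'
#' A mild latent correlation of 0.2 between BMI and HbA1c is the only
#' non-zero default dependence between continuous variables.
#'
#' @return A `population_spec`.
#' @export
default_table1_spec <- function() {
  cont <- list(
    age = list(mean = 58.2, sd = 10.2, lower = 40, upper = 79,
               family = "truncnorm"),
    bmi = list(mean = 33.6, sd = 7.95, lower = 15, upper = Inf,
               family = "truncnorm"),
    hba1c = list(mean = 7.3, sd = 1.95, lower = 4.5, upper = Inf,
                 family = "truncnorm"),
    fruit_servings = list(mean = 0.86, sd = 1.08, lower = 0, upper = Inf,
                          family = "gamma"),
    veg_servings = list(mean = 1.30, sd = 1.04, lower = 0, upper = Inf,
                        family = "gamma"))
  vars <- names(cont)
  R <- diag(length(vars)); dimnames(R) <- list(vars, vars)
  R["bmi", "hba1c"] <- R["hba1c", "bmi"] <- 0.2
  insurance_raw <- c(private = 29.4, medicare = 26.9, medicaid = 26.9,
                     dual = 12.5, none = 16.5)
  cat <- list(
    sex = c(female = 0.556, male = 0.444),
    race_ethnicity = c("NH-White" = 0.431, "NH-Black" = 0.172,
                       "Hispanic" = 0.290, "Other" = 0.107),
    education = c("<HS" = 0.371, "HS/GED" = 0.265, "some-college+" = 0.364),
    income_poverty_ratio = c("<1.30" = 0.566, "1.30-1.84" = 0.171,
                             "1.85-2.99" = 0.164, ">3.00" = 0.099),
    insurance = insurance_raw / sum(insurance_raw))
  spec <- population_spec(
    continuous = cont, categorical = cat, correlation = R,
    binary = c(hypertension = 0.748, cvd_history = 0.300,
               diabetes = 1.0, food_insecure = 1.0),
    cvd_subflags = c(angina = 0.158, chd = 0.119, mi = 0.128, stroke = 0.091),
    cvd_age_slope = 0.04)
  attr(spec, "insurance_raw") <- insurance_raw
  spec
}

## quantile of a normal truncated to [lower, upper]
qtruncnorm <- function(u, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, length(u)))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

## mean and sd of N(mu, sigma) truncated to [lo, hi]
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  ## phi terms vanish at infinite bounds (dnorm(+-Inf) = 0)
  adb <- if (is.finite(b)) b * db else 0
  ada <- if (is.finite(a)) a * da else 0
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (ada - adb) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

## underlying normal parameters whose [lo, hi]-truncation has the target
## mean and sd (moment matching; the published table reports moments of the
## bounded sample, not of a latent unbounded normal)
truncnorm_params <- function(mean, sd, lo, hi) {
  obj <- function(par) {
    mom <- truncnorm_moments(par[1], exp(par[2]), lo, hi)
    (mom[["mean"]] - mean)^2 / sd^2 + (mom[["sd"]] - sd)^2 / sd^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj,
                      control = list(reltol = 1e-15, maxit = 5000))
  if (fit$value > 1e-8) {
    stop("cannot moment-match a truncated normal to mean ", mean, ", sd ", sd,
         " on [", lo, ", ", hi, "]")
  }
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

## marginal quantile function for one continuous spec entry
marginal_quantile <- function(u, m) {
  fam <- if (is.null(m$family)) "truncnorm" else m$family
  if (m$sd == 0) return(rep(m$mean, length(u)))
  switch(fam,
    truncnorm = {
      p <- truncnorm_params(m$mean, m$sd, m$lower, m$upper)
      qtruncnorm(u, p[["mu"]], p[["sigma"]], m$lower, m$upper)
    },
    gamma = {
      shape <- (m$mean / m$sd)^2
      rate <- m$mean / m$sd^2
      stats::qgamma(u, shape = shape, rate = rate)
    },
    stop("unknown marginal family: ", fam))
}

## conditional sub-flag probabilities q such that rejection sampling
## (condition on >= 1 flag) reproduces the target conditional marginals t:
## solve q_k = t_k * (1 - prod(1 - q)) by fixed point
solve_subflag_probs <- function(t_cond) {
  q <- t_cond
  for (i in 1:200) {
    q_new <- pmin(1, t_cond * (1 - prod(1 - q)))
    if (max(abs(q_new - q)) < 1e-12) break
    q <- q_new
  }
  q
}

#' Generate a survey-weighted synthetic cohort
#'
#' Samples `n` individual records from a [population_spec()] using a
#' latent-Gaussian (Gaussian-copula) construction for the continuous
#' variables: a multivariate standard normal draw with the spec's correlation
#' matrix is mapped through the normal CDF and then through each variable's
#' marginal quantile function (moment-matched truncated normal, or gamma for
#' the right-skewed diet variables), so marginals carry the target moments
#' while the latent dependence is preserved. Categorical variables are sampled from
#' their category probabilities; CVD history uses a logistic tilt in age
#' whose intercept is calibrated so the cohort-level marginal prevalence
#' matches the spec; sub-flags are sampled conditionally on CVD history with
#' probabilities solved so their population marginals match the spec, with
#' at least one sub-flag guaranteed per case. Survey weights are lognormal,
#' rescaled to sum to the represented-population total.
#'
#' Identical `(spec, n, seed)` triples yield identical cohorts.
#'
#' @param spec a `population_spec`.
#' @param n number of individuals (>= 1).
#' @param seed integer seed.
#' @return A `data.frame` with one row per individual and the columns of the
#'   individual record: `person_id`, `survey_weight`, `age`, `sex`,
#'   `race_ethnicity`, `education`, `income_poverty_ratio`, `insurance`,
#'   `food_insecure`, `diabetes`, `hypertension`, `cvd_history`, `angina`,
#'   `chd`, `mi`, `stroke`, `bmi`, `hba1c`, `fruit_servings`, `veg_servings`.
#' @export
generate_cohort <- function(spec, n, seed) {
  stopifnot(inherits(spec, "population_spec"), n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  vars <- names(spec$continuous)
  k <- length(vars)
  ## latent MVN via eigen square root (cov is a correlation matrix)
  es <- eigen(spec$correlation, symmetric = TRUE)
  A <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), k) %*% t(es$vectors)
  Z <- matrix(stats::rnorm(n * k), n, k) %*% A
  U <- stats::pnorm(Z)
  colnames(U) <- vars
  cohort <- data.frame(person_id = sprintf("p%06d", seq_len(n)),
                       stringsAsFactors = FALSE)
  for (v in vars) {
    cohort[[v]] <- marginal_quantile(U[, v], spec$continuous[[v]])
  }

  for (v in names(spec$categorical)) {
    p <- spec$categorical[[v]]
    cohort[[v]] <- names(p)[findInterval(stats::runif(n), cumsum(p),
                                         left.open = TRUE) + 1L]
  }

  cohort$hypertension <- stats::runif(n) < spec$binary[["hypertension"]]
  cohort$diabetes <- stats::runif(n) < spec$binary[["diabetes"]]
  cohort$food_insecure <- stats::runif(n) < spec$binary[["food_insecure"]]

  ## CVD history: logistic in age, intercept calibrated so the simple mean
  ## of individual probabilities equals the marginal prevalence
  p_cvd <- spec$binary[["cvd_history"]]
  b <- spec$cvd_age_slope
  age_c <- cohort$age - mean(cohort$age)
  a <- stats::uniroot(function(a) mean(stats::plogis(a + b * age_c)) - p_cvd,
                      interval = c(-20, 20), tol = 1e-12)$root
  cohort$cvd_history <- stats::runif(n) < stats::plogis(a + b * age_c)

  ## sub-flags: conditional probabilities chosen so that, after rejection
  ## (every case carries >= 1 flag), population marginals match the spec
  t_cond <- spec$cvd_subflags / p_cvd
  if (any(t_cond > 1)) stop("sub-flag prevalence exceeds cvd_history prevalence")
  q <- solve_subflag_probs(t_cond)
  flags <- matrix(FALSE, n, 4, dimnames = list(NULL, names(spec$cvd_subflags)))
  idx <- which(cohort$cvd_history)
  if (length(idx)) {
    todo <- idx
    for (iter in 1:1000) {
      draw <- matrix(stats::runif(length(todo) * 4), ncol = 4) <
        matrix(q, length(todo), 4, byrow = TRUE)
      flags[todo, ] <- draw
      todo <- todo[rowSums(draw) == 0]
      if (!length(todo)) break
    }
    if (length(todo)) flags[todo, which.max(q)] <- TRUE  # unreachable in practice
  }
  cohort$angina <- flags[, "angina"]; cohort$chd <- flags[, "chd"]
  cohort$mi <- flags[, "mi"]; cohort$stroke <- flags[, "stroke"]

  w <- stats::rlnorm(n, spec$weight_meanlog, spec$weight_sdlog)
  cohort$survey_weight <- w / sum(w) * spec$total_population

  cols <- c("person_id", "survey_weight", "age", "sex", "race_ethnicity",
            "education", "income_poverty_ratio", "insurance", "food_insecure",
            "diabetes", "hypertension", "cvd_history", "angina", "chd", "mi",
            "stroke", "bmi", "hba1c", "fruit_servings", "veg_servings")
  cohort[, cols]
}

#' Survey-weighted summary of a cohort
#'
#' Computes survey-weighted means and SDs for the continuous variables and
#' weighted percentages for the categorical and binary variables, in the
#' layout of a baseline-characteristics table.
#'
#' @param cohort a cohort `data.frame` as returned by [generate_cohort()].
#' @return A `data.frame` with columns `variable`, `level`, `statistic`
#'   (`"mean"`, `"sd"` or `"percent"`) and `value`.
#' @export
weighted_summary <- function(cohort) {
  if (nrow(cohort) == 0) stop("cohort is empty")
  w <- cohort$survey_weight
  if (any(w <= 0)) stop("survey weights must be positive")
  rows <- list()
  add <- function(variable, level, statistic, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, level = level, statistic = statistic,
      value = value, stringsAsFactors = FALSE)
  }
  wmean <- function(x) sum(w * x) / sum(w)
  wsd <- function(x) sqrt(sum(w * (x - wmean(x))^2) / sum(w))
  for (v in c("age", "bmi", "hba1c", "fruit_servings", "veg_servings")) {
    add(v, NA_character_, "mean", wmean(cohort[[v]]))
    add(v, NA_character_, "sd", wsd(cohort[[v]]))
  }
  for (v in c("sex", "race_ethnicity", "education", "income_poverty_ratio",
              "insurance")) {
    tab <- tapply(w, cohort[[v]], sum)
    tab[is.na(tab)] <- 0
    pct <- 100 * tab / sum(w)
    for (lv in names(pct)) add(v, lv, "percent", unname(pct[lv]))
  }
  for (v in c("food_insecure", "diabetes", "hypertension", "cvd_history",
              "angina", "chd", "mi", "stroke")) {
    add(v, NA_character_, "percent", 100 * wmean(as.numeric(cohort[[v]])))
  }
  do.call(rbind, rows)
}

#' Validate individual-record invariants on a cohort
#'
#' Checks every row against the record invariants: positive survey weight,
#' age within 40-79 at baseline, diabetes and food insecurity universal,
#' CVD history consistent with its sub-flags, and physiologic bounds on BMI
#' and HbA1c.
#'
#' @param cohort a cohort `data.frame`.
#' @return Invisibly `TRUE`; stops with a message naming the first violated
#'   invariant otherwise.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  chk <- function(ok, msg) if (!all(ok)) stop("invariant violated: ", msg)
  chk(cohort$survey_weight > 0, "survey_weight > 0")
  chk(cohort$age >= 40 & cohort$age <= 79, "40 <= age <= 79")
  chk(cohort$diabetes, "diabetes universal at baseline")
  chk(cohort$food_insecure, "food insecurity universal at baseline")
  any_flag <- cohort$angina | cohort$chd | cohort$mi | cohort$stroke
  chk(cohort$cvd_history == any_flag,
      "cvd_history true iff at least one sub-flag")
  chk(cohort$bmi > 10, "bmi > 10")
  chk(cohort$hba1c >= 4 & cohort$hba1c <= 18, "hba1c in [4, 18]")
  chk(cohort$fruit_servings >= 0 & cohort$veg_servings >= 0,
      "servings nonnegative")
  invisible(TRUE)
}

#' Read / write a cohort as CSV
#'
#' One row per individual, header names exactly the individual-record field
#' names, booleans encoded 0/1, categories as literal labels.
#'
#' @param cohort a cohort `data.frame`.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   cohort `data.frame` with boolean columns restored.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (v in c("food_insecure", "diabetes", "hypertension", "cvd_history",
              "angina", "chd", "mi", "stroke")) {
    out[[v]] <- as.integer(out[[v]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (v in c("food_insecure", "diabetes", "hypertension", "cvd_history",
              "angina", "chd", "mi", "stroke")) {
    x[[v]] <- as.logical(x[[v]])
  }
  x
}
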