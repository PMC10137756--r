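#' DLBCL-like covariate schema
#'
#' The stock schema used by the simulator: age and LDH as continuous
#' covariates; sex, ECOG performance status (1-4), number of extranodal
#' sites (0-6), bone-marrow involvement, B symptoms, Ann Arbor stage (I-IV)
#' and IPI score (0-5) as pretreatment categorical covariates; and the
#' interim-PET Deauville score (1-5) as the sole on-treatment covariate.
#' Ordinal levels are listed in severity order.
#'
#' @return A [feature_schema()].
#' @export
dlbcl_schema <- function() {
  feature_schema(
    tibble(
      name = c("age", "ldh", "sex", "ecog", "extranodal", "bone_marrow",
               "b_symptoms", "stage", "ipi", "deauville"),
      role = c("continuous", "continuous", rep("categorical", 8)),
      levels = list(
        NULL, NULL,
        c("Female", "Male"),
        c("1", "2", "3", "4"),
        c("0", "1", "2", "3", "4", "5", "6"),
        c("No", "Yes"),
        c("No", "Yes"),
        c("I", "II", "III", "IV"),
        c("0", "1", "2", "3", "4", "5"),
        c("1", "2", "3", "4", "5")
      ),
      stage = c(rep("pretreatment", 9), "on-treatment")
    ),
    duration = "time_days", event = "event"
  )
}

# Marginal level probabilities of the simulated cohort (category counts of a
# 604-patient DLBCL cohort, normalized).
dlbcl_level_probs <- function() {
  list(
    sex = c(250, 354) / 604,
    ecog = c(323, 201, 66, 14) / 604,
    extranodal = c(166, 291, 120, 20, 3, 3, 1) / 604,
    bone_marrow = c(556, 48) / 604,
    b_symptoms = c(505, 99) / 604,
    stage = c(118, 196, 137, 153) / 604,
    ipi = c(81, 152, 135, 131, 77, 28) / 604,
    deauville = c(290, 108, 87, 75, 44) / 604
  )
}

# Standardization constants under which continuous effect sizes are declared:
# one unit of the standardized covariate, not one raw unit.
cont_standardizers <- function() {
  list(age = function(a) (a - 58.5) / 13,
       ldh = function(l) (log(l) - log(280)) / 0.6)
}

#' Simulation scenarios
#'
#' A scenario bundles the covariate-generating schema and marginals, a true
#' log-hazard function, a Weibull baseline and a target censoring fraction.
#'
#' `linear_ph_scenario()` is linear in the standardized continuous covariates
#' and in the ordinal level codes (constant per-step ladders), under a
#' Weibull proportional-hazards baseline and 70.86% target censoring — the
#' censoring rate of the 604-patient training cohort the simulator emulates.
#'
#' `interaction_scenario()` adds structure no linear-in-codes model can
#' capture: a non-linear Deauville severity ladder (the 4-5 jump far larger
#' than 1-2-3 steps), a stage x Deauville interaction (advanced stage with
#' Deauville 4-5 multiplies hazard beyond the main effects), and a
#' non-monotone (quadratic) LDH effect. Its target censoring is 50% so that
#' test sets stay event-rich for ranking comparisons.
#'
#' @param target_censoring Fraction of records to censor, in `[0, 1)`.
#' @return A `simulation_scenario`.
#' @export
linear_ph_scenario <- function(target_censoring = 0.7086) {
  new_scenario(
    name = "linear-ph",
    cont_slopes = c(age = 0.25, ldh = 0.30),
    level_values = list(
      sex = c(0, 0.25),
      ecog = 0.35 * (0:3),
      extranodal = 0.15 * (0:6),
      bone_marrow = c(0, 0.45),
      b_symptoms = c(0, 0.25),
      stage = 0.30 * (0:3),
      ipi = 0.20 * (0:5),
      deauville = 0.35 * (0:4)
    ),
    interaction = 0,
    ldh_quadratic = 0,
    target_censoring = target_censoring
  )
}

#' @rdname linear_ph_scenario
#' @export
interaction_scenario <- function(target_censoring = 0.5) {
  new_scenario(
    name = "interaction",
    cont_slopes = c(age = 0.25, ldh = 0),
    level_values = list(
      sex = c(0, 0.25),
      ecog = 0.30 * (0:3),
      extranodal = 0.12 * (0:6),
      bone_marrow = c(0, 0.40),
      b_symptoms = c(0, 0.25),
      stage = c(0, 0.15, 0.35, 0.55),
      ipi = 0.15 * (0:5),
      deauville = c(0, 0.10, 0.20, 1.10, 1.50)
    ),
    interaction = 1.6,
    ldh_quadratic = 1.1,
    target_censoring = target_censoring,
    # faster baseline than the linear scenario: the centred non-linear terms
    # stretch the right tail, and a 1600-day null median keeps the
    # administrative-cap censoring floor well below the 50% target
    weibull_scale = log(2) / 1600^1.2
  )
}

new_scenario <- function(name, cont_slopes, level_values, interaction,
                         ldh_quadratic, target_censoring,
                         weibull_shape = 1.2, weibull_scale = NULL,
                         admin_cap = 3000) {
  if (target_censoring < 0 || target_censoring >= 1) {
    abort("target_censoring must be in [0, 1)")
  }
  probs <- dlbcl_level_probs()
  stopifnot(all(abs(vapply(probs, sum, 1) - 1) < 1e-9))
  # baseline scale set so that a null-risk patient's median survival is
  # ~2500 days, inside the follow-up window the admin cap represents
  if (is.null(weibull_scale)) weibull_scale <- log(2) / 2500^weibull_shape
  stopifnot(weibull_shape > 0, weibull_scale > 0)
  structure(
    list(name = name, schema = dlbcl_schema(), level_probs = probs,
         cont_slopes = cont_slopes, level_values = level_values,
         interaction = interaction, ldh_quadratic = ldh_quadratic,
         target_censoring = target_censoring,
         weibull_shape = weibull_shape, weibull_scale = weibull_scale,
         admin_cap = admin_cap, age_range = c(36, 81)),
    class = "simulation_scenario"
  )
}

# True log hazard r for a covariate tibble on the label scale.
scenario_log_hazard <- function(scenario, df) {
  std <- cont_standardizers()
  r <- scenario$cont_slopes[["age"]] * std$age(df$age) +
    scenario$cont_slopes[["ldh"]] * std$ldh(df$ldh)
  sch <- scenario$schema
  for (nm in names(scenario$level_values)) {
    lv <- schema_cat(sch)$levels[[match(nm, schema_cat(sch)$name)]]
    r <- r + scenario$level_values[[nm]][match(df[[nm]], lv)]
  }
  if (scenario$interaction != 0) {
    r <- r + scenario$interaction *
      (df$stage %in% c("III", "IV")) * (df$deauville %in% c("4", "5"))
  }
  if (scenario$ldh_quadratic != 0) {
    z <- std$ldh(df$ldh)
    r <- r + scenario$ldh_quadratic * (z^2 - 1)
  }
  r - mean(r)
}

#' Per-covariate linear effect sizes of a scenario
#'
#' The least-squares slope of each feature's level values against its codes
#' (exact for linear ladders), plus the continuous slopes — the "true beta"
#' a linear-in-codes model should recover on a linear scenario.
#'
#' @param scenario A `simulation_scenario`.
#' @return Named numeric vector over covariates.
#' @export
scenario_true_beta <- function(scenario) {
  slopes <- vapply(scenario$level_values, function(v) {
    code <- seq_along(v) - 1
    stats::cov(code, v) / stats::var(code)
  }, 1)
  c(scenario$cont_slopes, slopes)
}

#' Simulate a DLBCL-like cohort with calibrated censoring
#'
#' Covariates are drawn from the scenario's marginals (age uniform over the
#' cohort's range, LDH log-normal clamped to the observed range, category
#' levels per the level probabilities). Event times follow the Weibull
#' proportional-hazards model: `T = (-log U / (lambda exp(r)))^(1/kappa)`
#' with `r` the true log hazard. An independent exponential censoring time,
#' capped at the administrative follow-up limit, is applied; its rate is
#' calibrated by root-finding on the drawn event times so the expected
#' censored fraction equals `target_censoring`. Observed time is
#' `min(T, C)` and `d = 1{T <= C}`.
#'
#' @param scenario A `simulation_scenario`.
#' @param n Cohort size.
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A `survival_dataset` with the true log-hazard vector attached as
#'   `$true_risk` for oracle evaluation.
#' @export
simulate_cohort <- function(scenario, n, seed) {
  withr::with_seed(seed, {
    df <- tibble(id = sprintf("SIM%05d", seq_len(n)))
    df$age <- runif(n, scenario$age_range[1], scenario$age_range[2])
    df$ldh <- pmin(pmax(rlnorm(n, log(280), 0.6), 144), 8402)
    sch_cat <- schema_cat(scenario$schema)
    for (i in seq_len(nrow(sch_cat))) {
      nm <- sch_cat$name[i]
      lv <- sch_cat$levels[[i]]
      df[[nm]] <- sample(lv, n, replace = TRUE,
                         prob = scenario$level_probs[[nm]])
    }
    r <- scenario_log_hazard(scenario, df)
    U <- runif(n)
    Tev <- (-log(U) / (scenario$weibull_scale * exp(r)))^(1 / scenario$weibull_shape)
    cap <- scenario$admin_cap
    # expected censored fraction as a function of the exponential rate,
    # conditional on the drawn event times; monotone increasing in rate
    frac <- function(rate) {
      mean(ifelse(Tev > cap, 1, 1 - exp(-rate * pmin(Tev, cap))))
    }
    target <- scenario$target_censoring
    if (frac(0) > target + 1e-12) {
      abort("target censoring below the administrative-cap floor: unreachable")
    }
    hi <- 1 / stats::median(Tev)
    while (frac(hi) < target && hi < 1e6) hi <- hi * 4
    if (frac(hi) < target) abort("censoring calibration failed to bracket target")
    rate <- if (target <= frac(0) + 1e-12) 0 else {
      uniroot(function(x) frac(x) - target, c(0, hi), tol = 1e-12)$root
    }
    C <- pmin(if (rate > 0) rexp(n, rate) else rep(Inf, n), cap)
    t_obs <- pmin(Tev, C)
    d <- as.integer(Tev <= C)
    df[[scenario$schema$duration]] <- pmax(t_obs, 1e-3)
    df[[scenario$schema$event]] <- d
    ds <- survival_dataset(df, scenario$schema)
    ds$true_risk <- r
    ds
  })
}

#' Read / write a simulation scenario as YAML
#'
#' Serializes the numeric content of a scenario (slopes, ladders,
#' interaction, censoring target, Weibull baseline); the schema and level
#' probabilities are the stock DLBCL-like ones.
#'
#' @param scenario A `simulation_scenario`.
#' @param path File path.
#' @return `read_scenario()` returns a `simulation_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(list(
    name = scenario$name,
    cont_slopes = as.list(scenario$cont_slopes),
    level_values = purrr::map(scenario$level_values, as.list),
    interaction = scenario$interaction,
    ldh_quadratic = scenario$ldh_quadratic,
    target_censoring = scenario$target_censoring,
    weibull_shape = scenario$weibull_shape,
    weibull_scale = scenario$weibull_scale,
    admin_cap = scenario$admin_cap
  ), path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  sc <- new_scenario(
    name = doc$name,
    cont_slopes = unlist(doc$cont_slopes),
    level_values = purrr::map(doc$level_values, unlist),
    interaction = doc$interaction,
    ldh_quadratic = doc$ldh_quadratic,
    target_censoring = doc$target_censoring,
    weibull_shape = doc$weibull_shape,
    weibull_scale = doc$weibull_scale,
    admin_cap = doc$admin_cap
  )
  sc
}
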