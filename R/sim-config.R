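#' Simulation configuration for synthetic two-arm cohorts
#'
#' Defines the data-generating process the analysis assumes: baseline
#' covariates, confounded treatment assignment through a logit model,
#' mixture (cure-fraction) survival with Weibull short-term deaths and a
#' long-term survivor fraction, per-category monthly cost rates with an
#' upfront drug-of-interest cost in the treated arm and a terminal-phase
#' uplift, second-/third-line progression events, and administrative
#' censoring from a uniform accrual window. Defaults emulate a two-arm
#' second-line immunotherapy cohort of 140 controls and 189 treated
#' patients whose survival curves flatten below a 15% plateau.
#'
#' @param n_control,n_treated target arm sizes; the treatment indicator is
#'   drawn per patient from a logit whose intercept reproduces the target
#'   marginal proportion, so realized arm sizes vary around the targets.
#' @param covariate_params named list of covariate distribution settings
#'   (see defaults in the function body; all members can be overridden).
#' @param assignment_coefs named log-odds coefficients of the assignment
#'   logit on standardized covariates: `age_z`, `morbidity_z`, `urban`,
#'   `prior_radiation`, `firstline_braf_mek`, `months_dx_z`. All-zero
#'   coefficients give unconfounded assignment at the target proportion.
#' @param survival_params list with per-arm `cure` (long-term survivor
#'   fraction, must be in \[0, 0.15\]), Weibull `shape` and `scale` (days)
#'   for short-term deaths, and accelerated-failure covariate effects
#'   `beta_age`, `beta_morbidity` (log time-ratio per SD) shared by both
#'   arms.
#' @param cost_params list: `monthly_rates` (named per-category CAD/30
#'   days, one vector per arm), `drug_cost_per_dose` and `drug_dose_days`
#'   (upfront drug-of-interest schedule, treated arm only),
#'   `terminal_uplift` (rate multiplier in the last 6 months of life),
#'   `noise_shape` (gamma shape of mean-one multiplicative cost noise).
#' @param progression_params list: per-arm mean/SD (days) of second-line
#'   treatment duration, per-arm third-line probability, and mean delay
#'   (days) from second-line end to third-line start.
#' @param censoring_params list: `enabled`, plus `cens_min`/`cens_max`
#'   bounds (days) of the per-patient uniform administrative-censoring
#'   time (the accrual window mapped to maximum follow-up).
#' @param horizon_days fixed 5-year horizon (1826 days).
#' @param discount_rate annual discount rate used for ground-truth
#'   estimands.
#' @param seed RNG seed used by [simulate_cohort()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_control = 140, n_treated = 189,
                       covariate_params = list(),
                       assignment_coefs = c(age_z = 0.8, morbidity_z = 0.4,
                                            urban = 0.2,
                                            prior_radiation = 0.2,
                                            firstline_braf_mek = 1.2,
                                            months_dx_z = -0.1),
                       survival_params = list(),
                       cost_params = list(),
                       progression_params = list(),
                       censoring_params = list(),
                       horizon_days = 1826,
                       discount_rate = 0.015,
                       seed = NULL) {
  cp <- utils::modifyList(list(
    age_mean = 58.5, age_sd = 18, age_min = 18, age_max = 95,
    p_male = 0.67,
    income_probs = c(0.11, 0.16, 0.22, 0.23, 0.28),
    p_urban = 0.89,
    morbidity_mean = 16, morbidity_sd = 16,
    adg_mean = 8.4, adg_sd = 3.3,
    p_charlson_1plus = 0.15,
    p_prior_radiation = 0.55,
    p_prior_resection = 0.56,
    firstline_probs = c(chemo = 0.70, braf_mek = 0.23, other = 0.07),
    months_dx_meanlog = log(21), months_dx_sdlog = 0.8
  ), covariate_params)

  sp <- utils::modifyList(list(
    control = list(cure = 0.06, shape = 1.2, scale = 170),
    treated = list(cure = 0.14, shape = 1.2, scale = 280),
    beta_age = -0.3, beta_morbidity = -0.15
  ), survival_params)

  kp <- utils::modifyList(list(
    monthly_rates = list(
      control = c(systemic_therapy = 2400, ambulatory = 1600,
                  inpatient = 1450, physician = 870, radiation = 455,
                  chronic_rehab = 235, laboratory = 14, homecare = 705),
      treated = c(systemic_therapy = 1900, ambulatory = 1500,
                  inpatient = 1150, physician = 730, radiation = 375,
                  chronic_rehab = 200, laboratory = 12, homecare = 330)),
    drug_cost_per_dose = 15000,
    drug_dose_days = c(0, 21, 42, 63),
    drug_category = "systemic_therapy",
    terminal_uplift = 1.5,
    noise_shape = 1.5
  ), cost_params)

  pp <- utils::modifyList(list(
    sl_mean = c(control = 100, treated = 85),
    sl_sd = c(control = 50, treated = 40),
    tl_prob = c(control = 0.35, treated = 0.30),
    tl_delay_mean = 60
  ), progression_params)

  zp <- utils::modifyList(list(
    enabled = TRUE, cens_min = 550, cens_max = 2400
  ), censoring_params)

  cfg <- structure(list(
    n_control = n_control, n_treated = n_treated,
    covariate_params = cp, assignment_coefs = assignment_coefs,
    survival_params = sp, cost_params = kp, progression_params = pp,
    censoring_params = zp, horizon_days = horizon_days,
    discount_rate = discount_rate, seed = seed), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid sim_config field '", field, "': ", why)
  }
  chk(cfg$n_control > 0 && cfg$n_treated > 0, "n_control/n_treated",
      "arm sizes must be positive")
  chk(cfg$horizon_days == 1826, "horizon_days",
      "the analysis horizon is fixed at 1826 days (5 years)")
  chk(cfg$discount_rate >= 0, "discount_rate", "must be nonnegative")
  for (a in c("control", "treated")) {
    s <- cfg$survival_params[[a]]
    chk(s$cure >= 0 && s$cure <= 0.15, paste0("survival_params$", a, "$cure"),
        "long-term survivor fraction must lie in [0, 0.15]")
    chk(s$shape > 0 && s$scale > 0, paste0("survival_params$", a),
        "Weibull shape and scale must be positive")
    chk(all(cfg$cost_params$monthly_rates[[a]] >= 0),
        paste0("cost_params$monthly_rates$", a),
        "cost rates must be nonnegative")
  }
  chk(all(cfg$cost_params$drug_cost_per_dose >= 0),
      "cost_params$drug_cost_per_dose", "must be nonnegative")
  chk(cfg$cost_params$terminal_uplift >= 1, "cost_params$terminal_uplift",
      "uplift multiplier must be >= 1")
  chk(cfg$censoring_params$cens_min >= 0 &&
        cfg$censoring_params$cens_max > cfg$censoring_params$cens_min,
      "censoring_params", "need 0 <= cens_min < cens_max")
  cp <- cfg$covariate_params
  chk(cp$age_sd > 0 && cp$morbidity_mean > 0 && cp$morbidity_sd > 0,
      "covariate_params", "age/morbidity scales must be positive")
  chk(abs(sum(cp$income_probs) - 1) < 1e-8, "covariate_params$income_probs",
      "must sum to 1")
  chk(abs(sum(cp$firstline_probs) - 1) < 1e-8,
      "covariate_params$firstline_probs", "must sum to 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_control, "control /", x$n_treated, "treated;",
      "horizon", x$horizon_days, "d; discount",
      sprintf("%.1f%%", 100 * x$discount_rate), "\n")
  cat("  cure fractions:", x$survival_params$control$cure, "/",
      x$survival_params$treated$cure,
      "; censoring", if (x$censoring_params$enabled)
        sprintf("U(%g, %g) d", x$censoring_params$cens_min,
                x$censoring_params$cens_max) else "disabled", "\n")
  invisible(x)
}
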