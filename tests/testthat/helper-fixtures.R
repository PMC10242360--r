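# Shared fixtures, built in code.

# Three-patient arm with a hand-computable censoring curve:
# deaths at day 45 and 100, censoring at day 75.
km_fixture <- function() {
  data.frame(patient_id = c("A", "B", "C"),
             arm = "control",
             followup_end = c(45, 75, 100),
             event = c(1, 0, 1),
             second_line_end = c(10, 10, 10),
             third_line_start = NA_real_,
             stringsAsFactors = FALSE)
}

# Deterministic two-arm cohort: outcomes constant within arm, with one
# noise covariate so the propensity model is estimable. Treated patients
# live longer and cost more by construction.
constant_cohort <- function(n_per_arm = 20, seed = 11) {
  set.seed(seed)
  n <- 2 * n_per_arm
  arm <- rep(c("control", "treated"), each = n_per_arm)
  fe <- ifelse(arm == "treated", 900, 400)
  data.frame(patient_id = sprintf("P%03d", seq_len(n)), arm = arm,
             x = rnorm(n), followup_end = fe, event = 1,
             second_line_end = 90, third_line_start = NA_real_,
             stringsAsFactors = FALSE)
}

constant_ledger <- function(cohort, control_cost = 10000,
                            treated_cost = 100000, drug_frac = 0.6) {
  tr <- cohort$arm == "treated"
  base <- data.frame(patient_id = cohort$patient_id, interval = 0L,
                     category = "systemic_therapy",
                     amount = ifelse(tr, treated_cost * (1 - drug_frac),
                                     control_cost),
                     drug_of_interest = FALSE, stringsAsFactors = FALSE)
  drug <- data.frame(patient_id = cohort$patient_id[tr], interval = 0L,
                     category = "systemic_therapy",
                     amount = treated_cost * drug_frac,
                     drug_of_interest = TRUE, stringsAsFactors = FALSE)
  rbind(base, drug)
}

# Study-sized simulated cohort + ledger with the default configuration.
sim_fixture <- function(seed = 42, ...) {
  cfg <- sim_config(seed = seed, ...)
  cohort <- simulate_cohort(cfg)
  list(config = cfg, cohort = cohort,
       ledger = simulate_cost_ledger(cohort, cfg))
}

# Configuration used for estimator-consistency checks: unconfounded
# assignment, longer survival, and a uniform administrative-censoring
# window over the whole horizon (roughly 30% of patients censored).
consistency_config <- function(n_per_arm, seed) {
  sim_config(
    n_control = n_per_arm, n_treated = n_per_arm,
    assignment_coefs = c(age_z = 0, morbidity_z = 0, urban = 0,
                         prior_radiation = 0, firstline_braf_mek = 0,
                         months_dx_z = 0),
    survival_params = list(control = list(cure = 0.10, shape = 1.2,
                                          scale = 400),
                           treated = list(cure = 0.14, shape = 1.2,
                                          scale = 600)),
    censoring_params = list(enabled = TRUE, cens_min = 0, cens_max = 1826),
    seed = seed)
}

# Approximate standard error of an IPTW-weighted arm-mean difference.
weighted_diff_se <- function(y, w, treated) {
  se_arm <- function(s) {
    m <- sum(w[s] * y[s]) / sum(w[s])
    sqrt(sum((w[s] * (y[s] - m))^2)) / sum(w[s])
  }
  sqrt(se_arm(treated)^2 + se_arm(!treated)^2)
}
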