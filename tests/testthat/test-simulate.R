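test_that("seeded simulation is reproducible", {
  cfg <- sim_config(seed = 404)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  expect_identical(simulate_cost_ledger(c1, cfg),
                   simulate_cost_ledger(c2, cfg))
  expect_equal(nrow(c1), 140 + 189)
})

test_that("invalid configurations are rejected by field name", {
  expect_error(sim_config(n_control = 0), "n_control")
  expect_error(sim_config(survival_params = list(
    control = list(cure = 0.3, shape = 1, scale = 100))), "cure")
  expect_error(sim_config(horizon_days = 1000), "horizon_days")
  expect_error(sim_config(cost_params = list(terminal_uplift = 0.5)),
               "terminal_uplift")
})

test_that("null assignment coefficients give the target treated fraction", {
  fx <- sim_fixture(seed = 7, n_control = 4260, n_treated = 5740,
                    assignment_coefs = c(age_z = 0))
  p_hat <- mean(fx$cohort$arm == "treated")
  p0 <- 5740 / 10000
  expect_lt(abs(p_hat - p0), 3 * sqrt(p0 * (1 - p0) / 10000))
})

test_that("the cure fraction sets the 5-year survival plateau", {
  cfg <- sim_config(n_control = 5000, n_treated = 5000,
                    survival_params = list(
                      control = list(cure = 0.10, shape = 1.2, scale = 170),
                      treated = list(cure = 0.10, shape = 1.2, scale = 280)),
                    censoring_params = list(enabled = FALSE), seed = 55)
  co <- simulate_cohort(cfg)
  alive <- mean(co$death_time > 1750)
  expect_lt(abs(alive - 0.10), 3 * sqrt(0.1 * 0.9 / 10000))
  # censoring disabled: follow-up ends in death or at the horizon
  expect_true(all(co$event == 1 | co$followup_end == 1826))
})

test_that("covariate means follow the configured distributions", {
  fx <- sim_fixture(seed = 66, n_control = 5000, n_treated = 5000)
  co <- fx$cohort
  n <- nrow(co)
  expect_lt(abs(mean(co$sex_male) - 0.67), 3 * sqrt(0.67 * 0.33 / n))
  expect_lt(abs(mean(co$urban) - 0.89), 3 * sqrt(0.89 * 0.11 / n))
  # age is lightly truncated to [18, 95]; allow a small systematic shift
  expect_lt(abs(mean(co$age) - 58.5), 0.6 + 3 * 18 / sqrt(n))
  expect_lt(abs(mean(co$morbidity) - 16), 3 * 16 / sqrt(n))
})

test_that("ledger entries stay inside observed follow-up", {
  fx <- sim_fixture(seed = 77)
  led <- fx$ledger
  pid <- match(led$patient_id, fx$cohort$patient_id)
  expect_true(all(led$interval * 30 < fx$cohort$followup_end[pid]))
  # a patient censored in the first interval has entries only there
  short <- fx$cohort$patient_id[fx$cohort$followup_end < 30]
  if (length(short)) {
    expect_true(all(led$interval[led$patient_id %in% short] == 0))
  }
})

test_that("degenerate rates isolate the upfront drug cost", {
  zero <- c(systemic_therapy = 0, ambulatory = 0, inpatient = 0,
            physician = 0, radiation = 0, chronic_rehab = 0,
            laboratory = 0, homecare = 0)
  fx <- sim_fixture(seed = 88, cost_params = list(
    monthly_rates = list(control = zero, treated = zero),
    drug_cost_per_dose = 40000, drug_dose_days = 0))
  led <- fx$ledger
  expect_true(all(led$drug_of_interest))
  tot <- tapply(led$amount, led$patient_id, sum)
  expect_true(all(tot == 40000))
  expect_true(all(fx$cohort$arm[match(names(tot),
                                      fx$cohort$patient_id)] == "treated"))
})

test_that("the terminal uplift doubles accrual in the last six months", {
  fx <- sim_fixture(
    seed = 91, n_control = 300, n_treated = 300,
    censoring_params = list(enabled = FALSE),
    cost_params = list(
      monthly_rates = list(control = c(ambulatory = 300),
                           treated = c(ambulatory = 300)),
      drug_cost_per_dose = 0, terminal_uplift = 2, noise_shape = NULL))
  co <- fx$cohort
  led <- fx$ledger
  dead <- co$patient_id[co$event == 1 & co$death_time > 400 &
                          co$death_time <= 1826]
  expect_gt(length(dead), 10)
  ok <- vapply(dead, function(p) {
    d <- co$death_time[co$patient_id == p]
    rows <- led[led$patient_id == p, ]
    full_term <- rows$interval * 30 >= d - 182.62 &
      (rows$interval + 1) * 30 <= d
    all(abs(rows$amount[full_term] - 600) < 1e-9)
  }, logical(1))
  expect_true(all(ok))
})

test_that("ground-truth estimands reduce to closed forms", {
  # zero costs everywhere -> zero incremental cost
  zero <- c(systemic_therapy = 0, ambulatory = 0, inpatient = 0,
            physician = 0, radiation = 0, chronic_rehab = 0,
            laboratory = 0, homecare = 0)
  cfg0 <- sim_config(seed = 2, cost_params = list(
    monthly_rates = list(control = zero, treated = zero),
    drug_cost_per_dose = 0))
  te0 <- true_estimands(cfg0, n_mc = 2000)
  expect_equal(te0$d_cost, 0)

  # identical survival in both arms -> zero incremental LY within MC error
  same <- list(control = list(cure = 0.08, shape = 1.2, scale = 200),
               treated = list(cure = 0.08, shape = 1.2, scale = 200))
  cfg1 <- sim_config(seed = 3, survival_params = same)
  te1 <- true_estimands(cfg1, n_mc = 20000)
  expect_lt(abs(te1$d_ly), 3 * te1$se_d_ly)

  # exponential survival, no discounting: E[min(T, T5)] = (1-e^(-lambda*T5))/lambda
  cfg2 <- sim_config(seed = 4, discount_rate = 0,
                     survival_params = list(
                       control = list(cure = 0, shape = 1, scale = 300),
                       treated = list(cure = 0, shape = 1, scale = 300),
                       beta_age = 0, beta_morbidity = 0))
  te2 <- true_estimands(cfg2, n_mc = 50000)
  closed <- 300 * (1 - exp(-1826 / 300)) / 365.25
  expect_lt(abs(te2$control["ly"] - closed), 3 * te2$control["se_ly"])
  expect_lt(abs(te2$treated["ly"] - closed), 3 * te2$treated["se_ly"])
  expect_equal(te2$icer, te2$d_cost / te2$d_ly)
})
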