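test_that("censoring curve is 1 everywhere without censoring events", {
  cc <- censoring_curve(c(100, 400, 1826), c(1, 1, 1))
  expect_true(all(cc$K == 1))
})

test_that("censoring curve matches the hand product-limit computation", {
  co <- km_fixture()
  cc <- censoring_curve(co$followup_end, co$event)
  expect_equal(cc$K[cc$starts %in% c(0, 30, 60)], rep(1, 3))
  expect_equal(cc$K[cc$starts == 90], 0.5) # risk set {B, C} at day 75
  expect_true(all(diff(cc$K) <= 0))
  expect_true(cc$K[1] == 1)
})

test_that("censoring curve agrees with survfit reverse KM on tie-free data", {
  skip_if_not_installed("survival")
  set.seed(5)
  fe <- round(runif(80, 1, 1700)) + runif(80) # no exact ties
  ev <- rbinom(80, 1, 0.6)
  cc <- censoring_curve(fe, ev)
  sf <- survival::survfit(survival::Surv(fe, 1 - ev) ~ 1)
  # left-continuous evaluation: value at the largest event time < t
  oracle <- vapply(cc$starts, function(s) {
    i <- which(sf$time < s & sf$n.event > 0)
    if (!length(i)) 1 else sf$surv[max(i)]
  }, numeric(1))
  expect_equal(cc$K, oracle, tolerance = 1e-12)
})

test_that("IPCW adjustment is the identity when no one is censored", {
  cc <- censoring_curve(c(50, 700), c(1, 1))
  contrib <- partition_followup(700)
  expect_equal(ipcw_adjust(contrib, cc, 700, 1), contrib)
})

test_that("censored patients contribute only fully observed intervals", {
  co <- km_fixture()
  cc <- censoring_curve(co$followup_end, co$event)
  contrib <- partition_followup(75)
  adj <- ipcw_adjust(contrib, cc, 75, 0)
  expect_equal(sum(adj), 60) # intervals [0,30) and [30,60) only
  adj_p <- ipcw_adjust(contrib, cc, 75, 0, include_partial = TRUE)
  expect_equal(sum(adj_p), 75) # partial interval kept, K still 1 there
})

test_that("the 3-patient arm reproduces the hand-computed adjusted mean", {
  co <- km_fixture()
  cc <- censoring_curve(co$followup_end, co$event)
  totals <- vapply(seq_len(3), function(i) {
    sum(ipcw_adjust(partition_followup(co$followup_end[i]), cc,
                    co$followup_end[i], co$event[i]))
  }, numeric(1))
  expect_equal(totals, c(45, 60, 110)) # day-100 death: 30+30+30+10/0.5
  expect_equal(mean(totals), 215 / 3)
})

test_that("an arm fully censored in the first interval is rejected", {
  co <- data.frame(patient_id = c("A", "B"), arm = "control",
                   followup_end = c(1, 1), event = 0,
                   second_line_end = 0, third_line_start = NA_real_)
  expect_error(adjusted_outcomes(co, NULL), "degenerate arm")
  cc <- censoring_curve(co$followup_end, co$event)
  expect_equal(cc$K[2], 0) # K hits 0 at day 30
  expect_error(ipcw_adjust(rep(1, 61), cc, 1826, 1), "reached 0")
})

test_that("with no censoring the estimator is the truncated sample mean", {
  fx <- sim_fixture(seed = 21,
                    censoring_params = list(enabled = FALSE))
  adj <- adjusted_outcomes(fx$cohort, fx$ledger, discount_rate = 0)
  naive <- pmin(fx$cohort$death_time, 1826) / 365.25
  for (a in c("control", "treated")) {
    s <- fx$cohort$arm == a
    expect_equal(mean(adj$ly[s]), mean(naive[s]), tolerance = 1e-12)
  }
})

test_that("adjusted outcomes without a ledger carry zero costs", {
  fx <- sim_fixture(seed = 31)
  adj <- adjusted_outcomes(fx$cohort, NULL)
  expect_true(all(adj$cost_total == 0))
  adj2 <- adjusted_outcomes(fx$cohort, fx$ledger)
  expect_equal(adj$ly, adj2$ly) # LY unaffected by costs
})

test_that("discounted totals are nonincreasing in the discount rate", {
  fx <- sim_fixture(seed = 8)
  rates <- c(0, 0.015, 0.03, 0.06)
  res <- lapply(rates, function(r)
    adjusted_outcomes(fx$cohort, fx$ledger, discount_rate = r))
  ly <- vapply(res, function(a) mean(a$ly), numeric(1))
  cost <- vapply(res, function(a) mean(a$cost_total), numeric(1))
  expect_true(all(diff(ly) < 0))
  expect_true(all(diff(cost) < 0))
})

test_that("cost ledger entries beyond follow-up are rejected", {
  co <- km_fixture()
  bad <- data.frame(patient_id = "A", interval = 5L,
                    category = "systemic_therapy", amount = 100,
                    drug_of_interest = FALSE)
  expect_error(adjusted_outcomes(co, bad), "beyond observed follow-up")
})
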