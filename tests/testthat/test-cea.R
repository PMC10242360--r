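test_that("incremental summary is treated minus control with sane ICERs", {
  adj <- data.frame(patient_id = 1:4,
                    arm = c("control", "control", "treated", "treated"),
                    ly = c(0.6, 0.8, 1.2, 1.4),
                    qaly = c(0.4, 0.6, 0.8, 1.0),
                    cost_total = c(60000, 70000, 150000, 160000),
                    cost_drug_of_interest = c(0, 0, 50000, 50000))
  s <- incremental_summary(adj)
  expect_equal(s$d_ly, 0.6)
  expect_equal(s$d_cost, 90000)
  expect_equal(s$icer_ly, 150000)
  # zero incremental effect: ICER undefined, not infinite
  adj$ly <- rep(1, 4)
  expect_true(is.na(incremental_summary(adj)$icer_ly))
  expect_error(incremental_summary(adj[adj$arm == "treated", ]),
               "both arms")
})

test_that("zero-variance fixture: every replicate equals the point estimate", {
  co <- constant_cohort()
  led <- constant_ledger(co)
  bt <- bootstrap_cea(co, led, B = 25, seed = 1, covariates = "x")
  expect_true(all(abs(bt$replicates$d_cost - bt$point$d_cost) < 1e-9))
  expect_true(all(abs(bt$replicates$d_ly - bt$point$d_ly) < 1e-9))
  # treated costlier and more effective by construction: all NE
  expect_equal(unname(bt$quadrants["NE"]), 25)
  expect_equal(sum(bt$quadrants), 25)
})

test_that("B = 1 without resampling reproduces the point estimate", {
  fx <- sim_fixture(seed = 14)
  bt <- bootstrap_cea(fx$cohort, fx$ledger, B = 1, seed = 2,
                      resample = FALSE)
  expect_equal(bt$replicates$d_cost, bt$point$d_cost, tolerance = 1e-12)
  expect_equal(bt$replicates$d_ly, bt$point$d_ly, tolerance = 1e-12)
  expect_equal(bt$replicates$d_qaly, bt$point$d_qaly, tolerance = 1e-12)
})

test_that("bootstrap is seeded and reports coherent intervals", {
  fx <- sim_fixture(seed = 17)
  b1 <- bootstrap_cea(fx$cohort, fx$ledger, B = 40, seed = 9)
  b2 <- bootstrap_cea(fx$cohort, fx$ledger, B = 40, seed = 9)
  expect_identical(b1$replicates, b2$replicates)
  expect_lt(b1$ci$d_cost[1], b1$ci$d_cost[2])
  expect_equal(sum(b1$quadrants), 40)
  if (b1$icer_ci_ly$defined) {
    expect_true(all(is.finite(b1$icer_ci_ly$ci)))
  }
})

test_that("CEAC equals the replicate-enumeration oracle", {
  bt <- structure(list(replicates = data.frame(
    d_cost = c(100, 300), d_ly = c(1, 1), d_qaly = c(1, 1))),
    class = "cea_bootstrap")
  cc <- ceac(bt, wtp = c(0, 200, 1e6))
  expect_equal(cc$prob, c(0, 0.5, 1))

  fx <- sim_fixture(seed = 25)
  bt <- bootstrap_cea(fx$cohort, fx$ledger, B = 60, seed = 3)
  wtp <- seq(0, 300000, by = 25000)
  cc <- ceac(bt, wtp = wtp)
  oracle <- vapply(wtp, function(l) {
    hits <- 0
    for (b in seq_len(nrow(bt$replicates))) {
      nb <- l * bt$replicates$d_ly[b] - bt$replicates$d_cost[b]
      if (nb > 0) hits <- hits + 1
    }
    hits / nrow(bt$replicates)
  }, numeric(1))
  expect_equal(cc$prob, oracle)
  if (all(bt$replicates$d_ly > 0)) {
    expect_true(all(diff(cc$prob) >= 0))
  }
})

test_that("net-benefit regression matches direct arithmetic", {
  adj <- data.frame(patient_id = 1:4,
                    arm = c("treated", "treated", "control", "control"),
                    ly = c(1.0, 1.0, 0.5, 0.5),
                    qaly = c(0.8, 0.8, 0.4, 0.4),
                    cost_total = c(50000, 50000, 20000, 20000))
  r <- nmb_regression(adj, lambda = 100000)
  expect_equal(r$estimate, 20000) # 100000*0.5 - 30000
  expect_true(r$cost_effective)
  r0 <- nmb_regression(adj, lambda = 0)
  expect_equal(r0$estimate, -30000) # lambda = 0: minus incremental cost
  expect_error(nmb_regression(adj[adj$arm == "treated", ], lambda = 0),
               "both arms")
})

test_that("incremental NMB is affine in WTP and crosses zero at the ICER", {
  fx <- sim_fixture(seed = 33)
  w <- iptw_weights(fit_propensity(fx$cohort), fx$cohort)
  adj <- adjusted_outcomes(fx$cohort, fx$ledger)
  s <- incremental_summary(adj, w)
  lams <- c(0, 50000, 100000, 200000, 300000)
  est <- vapply(lams, function(l)
    nmb_regression(adj, w, lambda = l)$estimate, numeric(1))
  expect_equal(est, -s$d_cost + lams * s$d_ly, tolerance = 1e-8)
  at_icer <- nmb_regression(adj, w, lambda = s$icer_ly)$estimate
  expect_lt(abs(at_icer), 1e-6 * abs(s$d_cost))
})

test_that("price reduction only rescales the tagged drug cost", {
  fx <- sim_fixture(seed = 37)
  w <- iptw_weights(fit_propensity(fx$cohort), fx$cohort)
  adj <- adjusted_outcomes(fx$cohort, fx$ledger)
  s <- incremental_summary(adj, w)
  pr <- price_reduction_curve(fx$cohort, fx$ledger,
                              fractions = seq(0, 1, 0.25), weights = w)
  expect_equal(pr$icer[1], s$icer_qaly, tolerance = 1e-12) # f = 0 identity
  expect_true(all(diff(pr$icer) <= 1e-9)) # nonincreasing in f
  # f = 1 removes exactly the weighted incremental drug cost
  drug_inc <- s$table$incremental[s$table$metric == "cost_drug_of_interest"]
  expect_equal(pr$d_cost[pr$fraction == 1], s$d_cost - drug_inc,
               tolerance = 1e-9)
  led <- fx$ledger
  led$drug_of_interest <- NULL
  expect_error(price_reduction_curve(fx$cohort, led), "drug_of_interest")
})

test_that("discounting is irrelevant when everything accrues at once", {
  co <- constant_cohort()
  co$followup_end <- ifelse(co$arm == "treated", 28, 14)
  co$second_line_end <- 5
  led <- constant_ledger(co)
  ds <- discount_sensitivity(co, led, rates = c(0, 0.015, 0.03),
                             covariates = "x")
  expect_lt(diff(range(ds$icer)) / abs(mean(ds$icer)), 1e-12)
})

test_that("base case sits inside its own sensitivity table", {
  fx <- sim_fixture(seed = 41)
  w <- iptw_weights(fit_propensity(fx$cohort), fx$cohort)
  adj <- adjusted_outcomes(fx$cohort, fx$ledger, discount_rate = 0.015)
  s <- incremental_summary(adj, w)
  ds <- discount_sensitivity(fx$cohort, fx$ledger, weights = w)
  expect_equal(ds$icer[ds$rate == 0.015], s$icer_ly, tolerance = 1e-12)
})

test_that("front-loaded incremental costs make the ICER rise with the rate", {
  # deterministic fixture: all incremental cost at day 0, survival
  # advantage accrued late
  co <- constant_cohort(n_per_arm = 30)
  led <- constant_ledger(co)
  ds <- discount_sensitivity(co, led, rates = c(0, 0.015, 0.03),
                             covariates = "x")
  expect_true(all(diff(ds$icer) > 0))
})
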