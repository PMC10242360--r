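null_coefs <- c(age_z = 0, morbidity_z = 0, urban = 0, prior_radiation = 0,
                firstline_braf_mek = 0, months_dx_z = 0)

test_that("null assignment yields null propensity coefficients", {
  fx <- sim_fixture(seed = 301, n_control = 5000, n_treated = 5000,
                    assignment_coefs = null_coefs)
  fit <- fit_propensity(fx$cohort)
  sm <- summary(fit$model)$coefficients
  z <- abs(sm[-1, "Estimate"] / sm[-1, "Std. Error"])
  expect_true(all(z < 3))
})

test_that("a known assignment log-odds is recovered", {
  set.seed(77)
  n <- 10000
  x <- rbinom(n, 1, 0.5)
  p <- plogis(-0.5 + 1.0 * x)
  co <- data.frame(patient_id = seq_len(n),
                   arm = ifelse(rbinom(n, 1, p) == 1, "treated", "control"),
                   x = x)
  fit <- fit_propensity(co, covariates = "x")
  sm <- summary(fit$model)$coefficients
  expect_lt(abs(sm["x", "Estimate"] - 1.0), 3 * sm["x", "Std. Error"])
})

test_that("degenerate covariates are dropped and separation is an error", {
  fx <- sim_fixture(seed = 5, n_control = 100, n_treated = 100)
  fx$cohort$const <- 1
  expect_warning(fit <- fit_propensity(fx$cohort, c("age", "const")),
                 "constant covariate")
  expect_false("const" %in% fit$covariates)
  fx$cohort$leak <- as.numeric(fx$cohort$arm == "treated")
  expect_error(fit_propensity(fx$cohort, "leak"), "separation")
  expect_error(fit_propensity(fx$cohort, c("age", "nope")), "nope")
})

test_that("IPTW closed forms hold at propensity one half", {
  n <- 10
  co <- data.frame(patient_id = seq_len(n),
                   arm = rep(c("control", "treated"), each = n / 2))
  fit <- structure(list(scores = rep(0.5, n)), class = "propensity_fit")
  w <- iptw_weights(fit, co)
  expect_true(all(w == 2))
  expect_equal(unname(attr(w, "weighted_n")), c(n, n))
  ws <- iptw_weights(fit, co, stabilized = TRUE)
  expect_true(all(ws[co$arm == "treated"] == 0.5 / 0.5))
  expect_true(all(ws[co$arm == "control"] == 0.5 / 0.5))
})

test_that("stabilized weights sum to roughly the arm sizes", {
  fx <- sim_fixture(seed = 13, n_control = 1000, n_treated = 1500)
  fit <- fit_propensity(fx$cohort)
  ws <- iptw_weights(fit, fx$cohort, stabilized = TRUE)
  wn <- attr(ws, "weighted_n")
  nn <- table(fx$cohort$arm)
  expect_lt(abs(wn["control"] - nn["control"]) / nn["control"], 0.1)
  expect_lt(abs(wn["treated"] - nn["treated"]) / nn["treated"], 0.1)
})

test_that("standardized differences have the published closed forms", {
  expect_equal(round(abs(std_diff_moments(57.5, 18.5, 59.5, 17.9)), 2),
               0.11)
  expect_equal(round(abs(std_diff_props(0.6663, 0.6771)), 2), 0.02)
  expect_equal(std_diff_moments(5, 2, 5, 2), 0)
  expect_error(std_diff_moments(5, 0, 6, 0), "zero pooled variance")
})

test_that("standardized difference is antisymmetric and affine-invariant", {
  set.seed(3)
  x1 <- rnorm(200, 1); x0 <- rnorm(300)
  w1 <- runif(200, 0.5, 2); w0 <- runif(300, 0.5, 2)
  d <- standardized_difference(x1, x0, w1, w0)
  expect_equal(standardized_difference(x0, x1, w0, w1), -d)
  expect_equal(standardized_difference(3 * x1 + 7, 3 * x0 + 7, w1, w0), d)
  expect_equal(standardized_difference(x1, x1, w1, w1), 0)
})

test_that("identity weights reproduce the unweighted balance table", {
  fx <- sim_fixture(seed = 19, n_control = 300, n_treated = 300)
  b1 <- balance_table(fx$cohort)
  b2 <- balance_table(fx$cohort, weights = rep(1, nrow(fx$cohort)))
  expect_equal(b1$std_diff, b2$std_diff)
  expect_true(all(b1$balanced == (abs(b1$std_diff) < 0.1)))
})

test_that("IPTW shrinks the imbalance of modeled confounders", {
  fx <- sim_fixture(seed = 23, n_control = 2000, n_treated = 2600)
  fit <- fit_propensity(fx$cohort)
  w <- iptw_weights(fit, fx$cohort)
  before <- balance_table(fx$cohort, covariates = c("age", "morbidity"))
  after <- balance_table(fx$cohort, w, covariates = c("age", "morbidity"))
  expect_true(all(abs(after$std_diff) < abs(before$std_diff)))
  expect_true(all(abs(after$std_diff) < 0.1))
  expect_true(any(abs(before$std_diff) > 0.1)) # confounding was real
})

test_that("ATE weighting recovers the pooled covariate mean in each arm", {
  fx <- sim_fixture(seed = 29, n_control = 4000, n_treated = 5000)
  co <- fx$cohort
  w <- iptw_weights(fit_propensity(co), co)
  pooled <- mean(co$age)
  for (a in c("control", "treated")) {
    s <- co$arm == a
    wm <- sum(w[s] * co$age[s]) / sum(w[s])
    se <- sd(co$age) / sqrt(sum(s))
    expect_lt(abs(wm - pooled), 4 * se)
  }
})

test_that("published summary rows flag imbalance exactly at the threshold", {
  rows <- data.frame(
    d = c(abs(std_diff_moments(57.5, 18.5, 59.5, 17.9)), # age
          abs(std_diff_props(0.6663, 0.6771)),           # males
          abs(std_diff_props(0.8853, 0.8912))))          # urban
  expect_equal(rows$d >= 0.1, c(TRUE, FALSE, FALSE))
})
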