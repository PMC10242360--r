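#' Weighted incremental cost-effectiveness summary
#'
#' IPTW-weighted per-arm means of discounted, censor-adjusted total cost,
#' per-category costs, life-years and QALYs, with incremental differences
#' (treated minus control) and the implied ICERs per life-year gained and
#' per QALY. An ICER with a zero incremental effect is reported as
#' undefined (`NA`), not infinite.
#'
#' @param adjout an [adjusted_outcomes()] data frame.
#' @param weights optional per-patient weights (e.g. [iptw_weights()]);
#'   default unit weights.
#' @return object of class `cea_summary`: `table` (metric, per-arm means,
#'   incremental), `d_cost`, `d_ly`, `d_qaly`, `icer_ly`, `icer_qaly`,
#'   `weighted_n`.
#' @export
incremental_summary <- function(adjout, weights = NULL) {
  stopifnot(is.data.frame(adjout),
            all(c("arm", "ly", "qaly", "cost_total") %in% names(adjout)))
  if (is.null(weights)) weights <- rep(1, nrow(adjout))
  stopifnot(length(weights) == nrow(adjout), all(weights >= 0))
  tr <- adjout$arm == "treated"
  if (!any(tr) || all(tr)) stop("both arms must be present")
  metrics <- c("ly", "qaly", "cost_total", "cost_drug_of_interest",
               grep("^cost_", names(adjout), value = TRUE))
  metrics <- unique(metrics[metrics %in% names(adjout)])
  wm <- function(x, s) sum(weights[s] * x[s]) / sum(weights[s])
  tab <- data.frame(
    metric = metrics,
    control = vapply(metrics, function(m) wm(adjout[[m]], !tr), 0),
    treated = vapply(metrics, function(m) wm(adjout[[m]], tr), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  tab$incremental <- tab$treated - tab$control
  g <- function(m, col) tab[[col]][tab$metric == m]
  d_ly <- g("ly", "incremental"); d_qaly <- g("qaly", "incremental")
  d_cost <- g("cost_total", "incremental")
  out <- list(table = tab, d_cost = d_cost, d_ly = d_ly, d_qaly = d_qaly,
              icer_ly = if (d_ly != 0) d_cost / d_ly else NA_real_,
              icer_qaly = if (d_qaly != 0) d_cost / d_qaly else NA_real_,
              weighted_n = c(control = sum(weights[!tr]),
                             treated = sum(weights[tr])))
  class(out) <- "cea_summary"
  out
}

#' @export
print.cea_summary <- function(x, ...) {
  cat(sprintf("Incremental cost-effectiveness (weighted N: %.1f control, %.1f treated)\n",
              x$weighted_n[1], x$weighted_n[2]))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) round(v, 3))
  print.data.frame(tab, row.names = FALSE)
  cat(sprintf("ICER: %s per LYG; %s per QALY\n",
              if (is.na(x$icer_ly)) "undefined" else sprintf("%.0f", x$icer_ly),
              if (is.na(x$icer_qaly)) "undefined" else sprintf("%.0f", x$icer_qaly)))
  invisible(x)
}

# -- internal fast path for the bootstrap -----------------------------------

cea_precompute <- function(cohort, ledger, covariates, iv, include_partial) {
  cohort <- validate_cohort(cohort)
  n <- nrow(cohort)
  treated <- cohort$arm == "treated"
  fe <- cohort$followup_end
  ev <- cohort$event
  ps <- progression_start(cohort$second_line_end, cohort$third_line_start,
                          fe, ev)
  Mly <- overlap_matrix(fe, iv)
  Mpf <- overlap_matrix(pmin(ps, fe), iv)
  if (!is.null(ledger)) {
    lm_ <- ledger_matrices(cohort, ledger, iv)
    cost <- Reduce(`+`, lm_$categories, matrix(0, n, iv$n))
    drug <- lm_$drug
  } else {
    cost <- drug <- matrix(0, n, iv$n)
  }
  X <- model.matrix(~ ., data = cohort[, covariates, drop = FALSE])
  list(n = n, treated = treated, fe = fe, event = ev, iv = iv,
       Mly = Mly, Mpf = Mpf, cost = cost, drug = drug, X = X,
       include_partial = include_partial)
}

# product-limit K at interval starts (censoring as event, death-first ties)
km_K <- function(followup_end, event, iv) {
  cens_times <- sort(unique(followup_end[event == 0]))
  if (!length(cens_times)) return(rep(1, iv$n))
  fac <- vapply(cens_times, function(u) {
    denom <- sum(followup_end >= u) - sum(followup_end == u & event == 1)
    1 - sum(followup_end == u & event == 0) / denom
  }, numeric(1))
  cumK <- cumprod(fac)
  idx <- vapply(iv$starts, function(s) sum(cens_times < s), integer(1))
  c(1, cumK)[idx + 1L]
}

replicate_cea <- function(pre, idx, u_pf, u_prog, disc, reestimate,
                          base_w = NULL) {
  tr <- pre$treated[idx]
  if (!any(tr) || all(tr)) stop("degenerate replicate: one arm empty")
  fe <- pre$fe[idx]; ev <- pre$event[idx]
  iv <- pre$iv
  m <- length(idx)
  K <- matrix(1, m, iv$n)
  for (a in c(FALSE, TRUE)) {
    sel <- tr == a
    K[sel, ] <- matrix(km_K(fe[sel], ev[sel], iv), sum(sel), iv$n,
                       byrow = TRUE)
  }
  keep <- keep_matrix(fe, ev, iv, pre$include_partial)
  Mly <- pre$Mly[idx, , drop = FALSE]
  if (any(keep & Mly > 0 & K <= 0)) {
    stop("K reached 0 where follow-up is observed")
  }
  adj <- keep / K * matrix(disc, m, iv$n, byrow = TRUE)
  adj[!keep | K <= 0] <- 0
  for (a in c(FALSE, TRUE)) {
    if (all((Mly * keep)[tr == a, ] == 0)) {
      stop("degenerate replicate: arm censored within first interval")
    }
  }
  ly_i <- rowSums(Mly * adj) / 365.25
  Mpf <- pre$Mpf[idx, , drop = FALSE]
  qaly_i <- rowSums((Mpf * u_pf + (Mly - Mpf) * u_prog) * adj) / 365.25
  cost_i <- rowSums(pre$cost[idx, , drop = FALSE] * adj)

  if (reestimate) {
    fit <- suppressWarnings(
      stats::glm.fit(pre$X[idx, , drop = FALSE], as.numeric(tr),
                     family = binomial()))
    e <- fit$fitted.values
    if (any(e < 1e-8) || any(e > 1 - 1e-8)) {
      stop("degenerate replicate: separation in propensity refit")
    }
    w <- ifelse(tr, 1 / e, 1 / (1 - e))
  } else {
    w <- if (is.null(base_w)) rep(1, m) else base_w[idx]
  }
  wm <- function(x, s) sum(w[s] * x[s]) / sum(w[s])
  c(d_cost = wm(cost_i, tr) - wm(cost_i, !tr),
    d_ly = wm(ly_i, tr) - wm(ly_i, !tr),
    d_qaly = wm(qaly_i, tr) - wm(qaly_i, !tr))
}

#' Bootstrap the incremental cost-effectiveness analysis
#'
#' Resamples patients with replacement, stratified by arm, and re-runs the
#' whole estimation inside each replicate: the propensity model is refit,
#' the per-arm censoring curves are re-estimated, utilities are redrawn
#' once per resampled patient, and the IPTW-weighted incremental cost and
#' effects are recomputed. Percentile 95% intervals are reported for the
#' incremental cost and effects; the ICER interval uses percentiles of the
#' replicate cost/effect ratios and is flagged undefined unless all
#' replicate incremental effects share one sign. Replicates with a
#' degenerate arm (empty, separated, or fully censored within the first
#' interval) are redrawn and counted.
#'
#' @inheritParams adjusted_outcomes
#' @param B number of bootstrap replicates (default 1000).
#' @param seed RNG seed for reproducibility.
#' @param resample set `FALSE` (with `B = 1`) to disable resampling and
#'   utility redraws; the replicate then reproduces the point estimate.
#' @param reestimate refit the propensity model and censoring curves in
#'   each replicate (default) or reuse the full-sample weights
#'   (weights-frozen mode).
#' @param covariates propensity-model covariates.
#' @param max_redraws cap on redrawn degenerate replicates.
#' @return object of class `cea_bootstrap`: `point` (the full-sample
#'   [incremental_summary()]), `replicates` (B rows of `d_cost`, `d_ly`,
#'   `d_qaly`), percentile `ci` entries, `icer_ci_ly` / `icer_ci_qaly`
#'   (with `defined` flags), CE-plane `quadrants` counts, `B`, `seed`,
#'   `n_redrawn`.
#' @export
bootstrap_cea <- function(cohort, ledger, B = 1000, seed = NULL,
                          resample = TRUE, reestimate = TRUE,
                          discount_rate = 0.015,
                          covariates = default_propensity_covariates(),
                          utility_params = rwcea::utility_params(),
                          include_partial = FALSE,
                          horizon_days = 1826, interval_days = 30,
                          max_redraws = 100) {
  stopifnot(B >= 1)
  if (!is.null(seed)) set.seed(seed)
  iv <- interval_grid(horizon_days, interval_days)
  disc <- discount_factor(iv$mids, discount_rate)
  pre <- cea_precompute(cohort, ledger, covariates, iv, include_partial)

  fit <- fit_propensity(cohort, covariates)
  w0 <- iptw_weights(fit, cohort)
  adj0 <- adjusted_outcomes(cohort, ledger, discount_rate = discount_rate,
                            utility_params = utility_params,
                            include_partial = include_partial,
                            horizon_days = horizon_days,
                            interval_days = interval_days)
  point <- incremental_summary(adj0, w0)

  u_mean_pf <- utility_params$pf_mean
  u_mean_pr <- max(utility_params$pf_mean - utility_params$dis_mean, 0)
  i_ctrl <- which(!pre$treated)
  i_trt <- which(pre$treated)

  reps <- matrix(NA_real_, B, 3,
                 dimnames = list(NULL, c("d_cost", "d_ly", "d_qaly")))
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- if (resample) {
        c(sample(i_ctrl, length(i_ctrl), replace = TRUE),
          sample(i_trt, length(i_trt), replace = TRUE))
      } else {
        seq_len(pre$n)
      }
      if (resample) {
        u <- sample_utilities(length(idx), utility_params)
        u_pf <- u$u_pf; u_pr <- u$u_prog
      } else {
        u_pf <- rep(u_mean_pf, length(idx))
        u_pr <- rep(u_mean_pr, length(idx))
      }
      r <- tryCatch(
        replicate_cea(pre, idx, u_pf, u_pr, disc, reestimate, w0),
        error = function(e) e)
      if (!inherits(r, "error")) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > max_redraws) {
        stop("too many degenerate bootstrap replicates: ",
             conditionMessage(r))
      }
    }
    reps[b, ] <- r
  }
  reps <- as.data.frame(reps)

  pci <- function(x) unname(quantile(x, c(0.025, 0.975)))
  icer_ci <- function(de) {
    if (all(de > 0) || all(de < 0)) {
      list(ci = pci(reps$d_cost / de), defined = TRUE)
    } else {
      list(ci = c(NA_real_, NA_real_), defined = FALSE)
    }
  }
  quad <- c(NE = sum(reps$d_ly > 0 & reps$d_cost > 0),
            SE = sum(reps$d_ly > 0 & reps$d_cost <= 0),
            SW = sum(reps$d_ly <= 0 & reps$d_cost <= 0),
            NW = sum(reps$d_ly <= 0 & reps$d_cost > 0))

  out <- list(point = point, replicates = reps,
              ci = list(d_cost = pci(reps$d_cost), d_ly = pci(reps$d_ly),
                        d_qaly = pci(reps$d_qaly)),
              icer_ci_ly = icer_ci(reps$d_ly),
              icer_ci_qaly = icer_ci(reps$d_qaly),
              quadrants = quad, B = B, seed = seed,
              n_redrawn = n_redrawn, resample = resample,
              reestimate = reestimate)
  class(out) <- "cea_bootstrap"
  out
}

#' @export
print.cea_bootstrap <- function(x, ...) {
  cat("Bootstrap CEA:", x$B, "replicates",
      if (x$n_redrawn) sprintf("(%d redrawn)", x$n_redrawn), "\n")
  cat(sprintf("  incremental cost %.0f (95%% CI %.0f to %.0f)\n",
              x$point$d_cost, x$ci$d_cost[1], x$ci$d_cost[2]))
  cat(sprintf("  incremental LY   %.3f (95%% CI %.3f to %.3f)\n",
              x$point$d_ly, x$ci$d_ly[1], x$ci$d_ly[2]))
  cat(sprintf("  incremental QALY %.3f (95%% CI %.3f to %.3f)\n",
              x$point$d_qaly, x$ci$d_qaly[1], x$ci$d_qaly[2]))
  if (x$icer_ci_ly$defined) {
    cat(sprintf("  ICER %.0f/LYG (95%% CI %.0f to %.0f)\n", x$point$icer_ly,
                x$icer_ci_ly$ci[1], x$icer_ci_ly$ci[2]))
  } else {
    cat("  ICER CI undefined (incremental effect changes sign across",
        "replicates); consider the net-benefit framing\n")
  }
  cat("  CE-plane quadrants:",
      paste(names(x$quadrants), x$quadrants, collapse = ", "), "\n")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold, the probability that the treated
#' strategy is cost-effective: the fraction of bootstrap replicates with
#' positive incremental net benefit `lambda * dE - dC`.
#'
#' @param boot a [bootstrap_cea()] result.
#' @param wtp willingness-to-pay grid (CAD per effect unit); default $0 to
#'   $300,000 in $1,000 steps.
#' @param measure effect measure: `"ly"` (default) or `"qaly"`.
#' @return data frame of class `ceac_curve`: `wtp`, `prob`.
#' @export
ceac <- function(boot, wtp = seq(0, 300000, by = 1000),
                 measure = c("ly", "qaly")) {
  measure <- match.arg(measure)
  stopifnot(inherits(boot, "cea_bootstrap"), all(wtp >= 0))
  de <- boot$replicates[[paste0("d_", measure)]]
  dc <- boot$replicates$d_cost
  prob <- vapply(wtp, function(l) mean(l * de - dc > 0), numeric(1))
  structure(data.frame(wtp = wtp, prob = prob),
            measure = measure, class = c("ceac_curve", "data.frame"))
}

#' Net-benefit regression at a willingness-to-pay threshold
#'
#' Computes each patient's net monetary benefit `lambda * effect - cost`
#' and regresses it on the treatment indicator by (IPTW-)weighted least
#' squares; the treatment coefficient is the incremental net monetary
#' benefit. The 95% interval uses heteroskedasticity-robust (HC0 sandwich)
#' standard errors. A positive incremental NMB means the treated strategy
#' is cost-effective at that threshold.
#'
#' @param adjout an [adjusted_outcomes()] data frame.
#' @param weights optional per-patient weights.
#' @param lambda willingness-to-pay threshold (CAD per effect unit, >= 0).
#' @param measure effect measure: `"ly"` (default) or `"qaly"`.
#' @return object of class `nmb_result`: `lambda`, `estimate`
#'   (incremental NMB), `se`, `ci`, `cost_effective`, `measure`.
#' @export
nmb_regression <- function(adjout, weights = NULL, lambda,
                           measure = c("ly", "qaly")) {
  measure <- match.arg(measure)
  stopifnot(lambda >= 0)
  if (is.null(weights)) weights <- rep(1, nrow(adjout))
  tr <- as.numeric(adjout$arm == "treated")
  if (all(tr == 0) || all(tr == 1)) stop("both arms required for NMB regression")
  nb <- lambda * adjout[[measure]] - adjout$cost_total
  dat <- data.frame(nb = nb, tr = tr, w = as.numeric(weights))
  fit <- lm(nb ~ tr, data = dat, weights = w)
  # suppress the 'perfect fit' note on degenerate (zero-residual) inputs
  V <- suppressWarnings(sandwich::vcovHC(fit, type = "HC0"))
  est <- unname(coef(fit)["tr"])
  se <- sqrt(V["tr", "tr"])
  ci <- est + qnorm(c(0.025, 0.975)) * se
  structure(list(lambda = lambda, estimate = est, se = se, ci = ci,
                 cost_effective = est > 0, measure = measure, model = fit),
            class = "nmb_result")
}

#' @export
print.nmb_result <- function(x, ...) {
  cat(sprintf(
    "Incremental NMB at WTP %.0f/%s: %.0f (95%% CI %.0f to %.0f) -> %s\n",
    x$lambda, toupper(x$measure), x$estimate, x$ci[1], x$ci[2],
    if (x$cost_effective) "cost-effective" else "not cost-effective"))
  invisible(x)
}

#' ICER as a function of the drug-of-interest price reduction
#'
#' Multiplies the ledger entries flagged `drug_of_interest` by
#' `(1 - fraction)` and re-runs the censor adjustment and weighted
#' incremental summary for each reduction fraction. Only the tagged drug
#' cost is rescaled, not the whole systemic-therapy category.
#'
#' @inheritParams adjusted_outcomes
#' @param fractions price-reduction fractions in \[0, 1\].
#' @param weights per-patient weights; when `NULL` a default propensity
#'   model is fitted once and ATE IPTW weights are used throughout.
#' @param measure effect measure for the reported ICER (`"qaly"` default).
#' @param covariates propensity covariates used when `weights` is `NULL`.
#' @return data frame: `fraction`, `d_cost`, `d_effect`, `icer`.
#' @export
price_reduction_curve <- function(cohort, ledger,
                                  fractions = seq(0, 1, by = 0.1),
                                  weights = NULL,
                                  measure = c("qaly", "ly"),
                                  discount_rate = 0.015,
                                  utility_params = rwcea::utility_params(),
                                  covariates = default_propensity_covariates(),
                                  include_partial = FALSE,
                                  horizon_days = 1826, interval_days = 30) {
  measure <- match.arg(measure)
  stopifnot(all(fractions >= 0), all(fractions <= 1))
  if (!"drug_of_interest" %in% names(ledger) ||
      !any(as.logical(ledger$drug_of_interest))) {
    stop("ledger carries no drug_of_interest entries; cannot rescale the ",
         "drug price")
  }
  if (is.null(weights)) {
    weights <- iptw_weights(fit_propensity(cohort, covariates), cohort)
  }
  rows <- lapply(fractions, function(f) {
    led <- ledger
    sel <- as.logical(led$drug_of_interest)
    led$amount[sel] <- led$amount[sel] * (1 - f)
    adj <- adjusted_outcomes(cohort, led, discount_rate = discount_rate,
                             utility_params = utility_params,
                             include_partial = include_partial,
                             horizon_days = horizon_days,
                             interval_days = interval_days)
    s <- incremental_summary(adj, weights)
    de <- if (measure == "qaly") s$d_qaly else s$d_ly
    data.frame(fraction = f, d_cost = s$d_cost, d_effect = de,
               icer = if (de != 0) s$d_cost / de else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "measure") <- measure
  out
}

#' Discount-rate sensitivity analysis
#'
#' Re-runs the censor-adjusted weighted analysis at each annual discount
#' rate and tabulates the incremental cost, incremental life-years and
#' ICER; with `B > 0`, bootstrap percentile intervals are added.
#'
#' @inheritParams price_reduction_curve
#' @param rates annual discount rates (default 0%, 1.5%, 3%).
#' @param B bootstrap replicates per rate (0 = point estimates only).
#' @param seed RNG seed used when `B > 0`.
#' @return data frame: `rate`, `d_cost`, `d_ly`, `icer` (and CI columns
#'   when `B > 0`).
#' @export
discount_sensitivity <- function(cohort, ledger,
                                 rates = c(0, 0.015, 0.03),
                                 weights = NULL, B = 0, seed = NULL,
                                 covariates = default_propensity_covariates(),
                                 utility_params = rwcea::utility_params(),
                                 include_partial = FALSE,
                                 horizon_days = 1826, interval_days = 30) {
  stopifnot(all(rates >= 0))
  if (is.null(weights)) {
    weights <- iptw_weights(fit_propensity(cohort, covariates), cohort)
  }
  rows <- lapply(rates, function(r) {
    adj <- adjusted_outcomes(cohort, ledger, discount_rate = r,
                             utility_params = utility_params,
                             include_partial = include_partial,
                             horizon_days = horizon_days,
                             interval_days = interval_days)
    s <- incremental_summary(adj, weights)
    row <- data.frame(rate = r, d_cost = s$d_cost, d_ly = s$d_ly,
                      icer = s$icer_ly)
    if (B > 0) {
      bt <- bootstrap_cea(cohort, ledger, B = B, seed = seed,
                          discount_rate = r, covariates = covariates,
                          utility_params = utility_params,
                          include_partial = include_partial,
                          horizon_days = horizon_days,
                          interval_days = interval_days)
      row$d_cost_lo <- bt$ci$d_cost[1]; row$d_cost_hi <- bt$ci$d_cost[2]
      row$d_ly_lo <- bt$ci$d_ly[1]; row$d_ly_hi <- bt$ci$d_ly[2]
      row$icer_lo <- bt$icer_ci_ly$ci[1]; row$icer_hi <- bt$icer_ci_ly$ci[2]
    }
    row
  })
  do.call(rbind, rows)
}
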