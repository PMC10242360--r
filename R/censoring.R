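#' Kaplan-Meier curve of remaining uncensored
#'
#' Estimates, within one treatment arm, the probability K(t) of not being
#' censored at the start of each 30-day interval by the product-limit
#' method with the roles of death and censoring reversed: censoring is the
#' event and death removes a patient from the risk set without an event.
#' K(t) is evaluated left-continuously (only censoring events strictly
#' before t reduce K(t)), and a death tied with a censoring on the same day
#' leaves the risk set before the censoring is counted.
#'
#' K(t) can only reach zero beyond the last time at which any patient
#' remains under observation, so the IPCW weights 1/K are well defined
#' wherever a patient contributes follow-up.
#'
#' @param followup_end per-patient end of observed follow-up (days).
#' @param event per-patient indicator: 1 if follow-up ended in death,
#'   0 if it ended by censoring (administrative or loss to follow-up).
#' @param arm optional arm label stored on the result.
#' @inheritParams interval_grid
#' @return object of class `censoring_curve`: list with `starts` (days),
#'   `K` (probability uncensored at each interval start), `arm`, `n`.
#' @examples
#' # deaths at day 45 and 100, censoring at day 75:
#' cc <- censoring_curve(c(45, 75, 100), c(1, 0, 1))
#' cc$K[cc$starts == 90]  # 0.5
#' @export
censoring_curve <- function(followup_end, event, arm = NULL,
                            horizon_days = 1826, interval_days = 30) {
  stopifnot(length(followup_end) == length(event))
  if (length(followup_end) == 0) stop("empty arm: no patients")
  if (!all(event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (death)")
  if (any(followup_end < 0)) stop("negative follow-up time")
  iv <- interval_grid(horizon_days, interval_days)

  cens_times <- sort(unique(followup_end[event == 0]))
  if (length(cens_times)) {
    fac <- vapply(cens_times, function(u) {
      at_risk <- sum(followup_end >= u)
      d_death <- sum(followup_end == u & event == 1)
      d_cens <- sum(followup_end == u & event == 0)
      denom <- at_risk - d_death # deaths leave the risk set first on ties
      1 - d_cens / denom
    }, numeric(1))
    cumK <- cumprod(fac)
    idx <- vapply(iv$starts, function(s) sum(cens_times < s), integer(1))
    K <- c(1, cumK)[idx + 1L]
  } else {
    K <- rep(1, iv$n)
  }
  structure(list(starts = iv$starts, K = K, arm = arm,
                 n = length(followup_end), interval_days = interval_days,
                 horizon_days = horizon_days),
            class = "censoring_curve")
}

#' @export
print.censoring_curve <- function(x, ...) {
  cat("Censoring curve", if (!is.null(x$arm)) paste0("(", x$arm, ")"),
      "- probability of remaining uncensored\n")
  cat("  n =", x$n, "patients;", length(x$starts), "interval starts;",
      "K(last start) =", signif(min(x$K), 4), "\n")
  invisible(x)
}

#' Inverse-probability-of-censoring adjustment of per-interval contributions
#'
#' Divides each interval's observed contribution (days alive, or cost) by
#' the arm's probability of remaining uncensored at the interval start.
#' Contributions of a censored patient in and after the interval containing
#' the censoring time are set to zero by default: the weight 1/K(start) is
#' valid for patients under observation through the whole interval.
#' `include_partial = TRUE` instead keeps the partial accrual in the
#' censoring interval (alternative convention).
#'
#' @param contrib numeric vector of per-interval raw contributions.
#' @param curve a [censoring_curve()] for the patient's arm.
#' @param followup_end the patient's end of follow-up (days).
#' @param event 1 if follow-up ended in death, 0 if censored.
#' @param include_partial keep the censored patient's partial interval?
#' @return adjusted per-interval contributions.
#' @export
ipcw_adjust <- function(contrib, curve, followup_end, event,
                        include_partial = FALSE) {
  stopifnot(inherits(curve, "censoring_curve"))
  K <- curve$K
  if (length(contrib) != length(K)) {
    stop("contrib must have one entry per interval (", length(K), ")")
  }
  ends <- pmin(curve$starts + curve$interval_days, curve$horizon_days)
  keep <- if (event == 1) {
    rep(TRUE, length(K))
  } else if (include_partial) {
    curve$starts < followup_end
  } else {
    ends <= followup_end
  }
  if (any(keep & contrib > 0 & K <= 0)) {
    stop("censoring probability K reached 0 where a contribution is ",
         "observed; truncate the horizon before this time")
  }
  out <- contrib * keep / K
  out[!keep | K <= 0] <- 0
  out
}

# -- vectorised engine ------------------------------------------------------

# n x K matrix of 'interval fully observed' indicators.
keep_matrix <- function(followup_end, event, iv, include_partial = FALSE) {
  n <- length(followup_end)
  starts <- matrix(iv$starts, n, iv$n, byrow = TRUE)
  ends <- matrix(iv$ends, n, iv$n, byrow = TRUE)
  fe <- matrix(followup_end, n, iv$n)
  keep <- if (include_partial) starts < fe else ends <= fe
  keep[event == 1, ] <- TRUE
  keep
}

validate_cohort <- function(cohort) {
  req <- c("patient_id", "arm", "followup_end", "event", "second_line_end")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) stop("cohort is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$patient_id)) stop("duplicate patient_id in cohort")
  if (!all(cohort$arm %in% c("control", "treated"))) {
    stop("arm must be 'control' or 'treated'")
  }
  if (!all(cohort$event %in% c(0, 1))) stop("event must be 0 or 1")
  if (any(cohort$followup_end < 0)) stop("negative followup_end")
  if (any(cohort$second_line_end > cohort$followup_end + 1e-9)) {
    stop("second_line_end after followup_end for patient(s): ",
         paste(head(cohort$patient_id[
           cohort$second_line_end > cohort$followup_end + 1e-9]),
           collapse = ", "))
  }
  if (!"third_line_start" %in% names(cohort)) cohort$third_line_start <- NA_real_
  tl <- cohort$third_line_start
  bad <- !is.na(tl) & (tl < 0 | tl > cohort$followup_end + 1e-9)
  if (any(bad)) {
    stop("third_line_start outside [0, followup_end] for patient(s): ",
         paste(head(cohort$patient_id[bad]), collapse = ", "))
  }
  invisible(cohort)
}

# cost ledger -> list of n x K matrices, one per category, plus drug matrix
ledger_matrices <- function(cohort, ledger, iv) {
  stopifnot(all(c("patient_id", "interval", "category", "amount") %in%
                  names(ledger)))
  if (nrow(ledger)) {
    if (any(ledger$interval < 0) || any(ledger$interval != floor(ledger$interval)))
      stop("ledger interval indices must be nonnegative integers")
    if (any(ledger$interval >= iv$n))
      stop("ledger entry beyond the analysis horizon")
    pid <- match(ledger$patient_id, cohort$patient_id)
    if (anyNA(pid)) stop("ledger references unknown patient_id")
    fe <- cohort$followup_end[pid]
    beyond <- iv$starts[ledger$interval + 1L] >= fe
    if (any(beyond)) {
      stop("cost ledger entries beyond observed follow-up for patient(s): ",
           paste(unique(head(ledger$patient_id[beyond])), collapse = ", "))
    }
  }
  n <- nrow(cohort)
  cats <- sort(unique(as.character(ledger$category)))
  mk <- function(sel) {
    m <- matrix(0, n, iv$n)
    if (any(sel)) {
      i <- match(ledger$patient_id[sel], cohort$patient_id)
      k <- ledger$interval[sel] + 1L
      cell <- (k - 1L) * n + i
      agg <- rowsum(ledger$amount[sel], cell)
      m[as.integer(rownames(agg))] <- agg
    }
    m
  }
  mats <- lapply(cats, function(cc) mk(ledger$category == cc))
  names(mats) <- cats
  drug <- if ("drug_of_interest" %in% names(ledger)) {
    mk(as.logical(ledger$drug_of_interest))
  } else {
    matrix(0, n, iv$n)
  }
  list(categories = mats, drug = drug)
}

#' Censor-adjusted, discounted patient-level outcomes
#'
#' The partitioned IPCW estimator: each patient's follow-up and costs are
#' partitioned over the 30-day grid, each interval's contribution is
#' divided by the arm-specific Kaplan-Meier probability of remaining
#' uncensored at the interval start ([censoring_curve()]), discounted at
#' the interval midpoint, and summed. Life-years are converted to years
#' (365.25 days); QALYs weight each interval's adjusted life-years by the
#' utility of the health state occupying it (time-weighted across a
#' progression boundary inside an interval).
#'
#' @param cohort data frame with columns `patient_id`, `arm`
#'   (`"control"`/`"treated"`), `followup_end` (days), `event` (1 death /
#'   0 censored), `second_line_end` (days), optional `third_line_start`.
#' @param ledger cost ledger data frame with columns `patient_id`,
#'   `interval` (0-based 30-day index), `category`, `amount` (CAD),
#'   optional `drug_of_interest` flag. May be `NULL` for effectiveness-only
#'   analyses.
#' @param discount_rate annual discount rate (default 0.015).
#' @param utilities optional data frame with per-patient columns `u_pf`,
#'   `u_prog` (rows aligned with `cohort`); default uses the means of
#'   `utility_params` for every patient.
#' @param utility_params a [utility_params()] list (used when
#'   `utilities` is `NULL`).
#' @param include_partial keep censored patients' partial interval
#'   (see [ipcw_adjust()]).
#' @param curves optional named list of pre-computed [censoring_curve()]s
#'   (`control`, `treated`); estimated from the cohort when `NULL`.
#' @inheritParams interval_grid
#' @return data frame of class `adjusted_outcomes`, one row per patient:
#'   `patient_id`, `arm`, `ly` and `qaly` (discounted, censor-adjusted
#'   years), `cost_total` and one `cost_<category>` column per ledger
#'   category (discounted, censor-adjusted CAD), `cost_drug_of_interest`.
#'   Attributes: `curves`, `discount_rate`, `grid`.
#' @export
adjusted_outcomes <- function(cohort, ledger = NULL, discount_rate = 0.015,
                              utilities = NULL,
                              utility_params = rwcea::utility_params(),
                              include_partial = FALSE, curves = NULL,
                              horizon_days = 1826, interval_days = 30) {
  cohort <- validate_cohort(cohort)
  if (any(cohort$followup_end > horizon_days)) {
    stop("followup_end beyond the analysis horizon; truncate to ",
         horizon_days, " days")
  }
  iv <- interval_grid(horizon_days, interval_days)
  n <- nrow(cohort)
  arms <- c("control", "treated")

  if (is.null(curves)) {
    curves <- lapply(setNames(arms, arms), function(a) {
      sel <- cohort$arm == a
      if (!any(sel)) return(NULL)
      censoring_curve(cohort$followup_end[sel], cohort$event[sel], arm = a,
                      horizon_days = horizon_days,
                      interval_days = interval_days)
    })
  }

  Kmat <- matrix(1, n, iv$n)
  for (a in arms) {
    sel <- cohort$arm == a
    if (any(sel)) Kmat[sel, ] <- matrix(curves[[a]]$K, sum(sel), iv$n,
                                        byrow = TRUE)
  }

  Mly <- overlap_matrix(cohort$followup_end, iv)
  keep <- keep_matrix(cohort$followup_end, cohort$event, iv, include_partial)
  if (any(keep & Mly > 0 & Kmat <= 0)) {
    stop("censoring probability K reached 0 where follow-up is observed; ",
         "truncate the horizon")
  }
  W <- keep / Kmat
  W[!keep | Kmat <= 0] <- 0 # K=0 only where contributions are zero (guarded)
  dmat <- matrix(discount_factor(iv$mids, discount_rate), n, iv$n,
                 byrow = TRUE)

  for (a in arms) {
    sel <- cohort$arm == a
    if (any(sel) && all((Mly * keep)[sel, ] == 0)) {
      stop("degenerate arm '", a, "': no uncensored follow-up observed ",
           "(all patients censored within the first interval)")
    }
  }

  adjly <- Mly * W * dmat
  ly <- rowSums(adjly) / 365.25

  # health-state split of alive-days per interval
  ps <- progression_start(cohort$second_line_end, cohort$third_line_start,
                          cohort$followup_end, cohort$event)
  pf_end <- pmin(ps, cohort$followup_end)
  Mpf <- overlap_matrix(pf_end, iv)
  Mpr <- Mly - Mpf

  if (is.null(utilities)) {
    u_pf <- rep(utility_params$pf_mean, n)
    u_prog <- rep(max(utility_params$pf_mean - utility_params$dis_mean, 0), n)
  } else {
    stopifnot(all(c("u_pf", "u_prog") %in% names(utilities)),
              nrow(utilities) == n)
    u_pf <- utilities$u_pf
    u_prog <- utilities$u_prog
  }
  qaly <- rowSums((Mpf * u_pf + Mpr * u_prog) * W * dmat) / 365.25

  out <- data.frame(patient_id = cohort$patient_id, arm = cohort$arm,
                    ly = ly, qaly = qaly, stringsAsFactors = FALSE)

  out$cost_total <- 0
  out$cost_drug_of_interest <- 0
  if (!is.null(ledger)) {
    lm_ <- ledger_matrices(cohort, ledger, iv)
    tot <- matrix(0, n, iv$n)
    for (cc in names(lm_$categories)) {
      adj <- lm_$categories[[cc]] * W * dmat
      out[[paste0("cost_", cc)]] <- rowSums(adj)
      tot <- tot + adj
    }
    out$cost_total <- rowSums(tot)
    out$cost_drug_of_interest <- rowSums(lm_$drug * W * dmat)
  }

  structure(out, curves = curves, discount_rate = discount_rate, grid = iv,
            include_partial = include_partial,
            class = c("adjusted_outcomes", "data.frame"))
}
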