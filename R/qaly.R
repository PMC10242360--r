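#' Utility distribution parameters
#'
#' Moments of the health-state utility distributions used to turn
#' life-years into QALYs: the progression-free utility and the disutility
#' decrement applied on progression, each sampled from a moment-matched
#' beta distribution. Defaults are the Canadian general-public weights used
#' in the base-case analysis (progression-free mean 0.79, SD 0.02;
#' disutility mean 0.24, SD 0.02).
#'
#' @param pf_mean,pf_sd mean and SD of the progression-free utility.
#' @param dis_mean,dis_sd mean and SD of the progression disutility.
#' @return list of class `utility_params`.
#' @export
utility_params <- function(pf_mean = 0.79, pf_sd = 0.02,
                           dis_mean = 0.24, dis_sd = 0.02) {
  stopifnot(pf_mean > 0, pf_mean < 1, pf_sd > 0,
            dis_mean > 0, dis_mean < 1, dis_sd > 0,
            pf_mean - dis_mean > 0, pf_mean - dis_mean < 1)
  structure(list(pf_mean = pf_mean, pf_sd = pf_sd,
                 dis_mean = dis_mean, dis_sd = dis_sd),
            class = "utility_params")
}

#' Beta shape parameters from a mean and standard deviation
#'
#' Method-of-moments parameterization: with
#' `nu = mean*(1-mean)/sd^2 - 1`, the shapes are `alpha = mean*nu` and
#' `beta = (1-mean)*nu`. Requires `sd^2 < mean*(1-mean)`.
#'
#' @param mean mean in (0, 1).
#' @param sd standard deviation (> 0).
#' @return named numeric vector `c(alpha, beta)`.
#' @examples
#' beta_from_moments(0.5, sqrt(1 / 12)) # c(1, 1): the uniform
#' beta_from_moments(0.79, 0.02)
#' @export
beta_from_moments <- function(mean, sd) {
  stopifnot(mean > 0, mean < 1, sd > 0)
  if (sd^2 >= mean * (1 - mean)) {
    stop("variance too large for a beta distribution: need sd^2 < mean*(1-mean)")
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Sample per-patient health-state utilities
#'
#' Draws, independently per patient, a progression-free utility and a
#' disutility from their moment-matched beta distributions; the progressed
#' utility is the difference, floored at zero. One draw per patient per
#' call (as in a single bootstrap iteration).
#'
#' @param n number of patients.
#' @param params a [utility_params()] list.
#' @return data frame with columns `u_pf`, `u_prog`.
#' @export
sample_utilities <- function(n, params = utility_params()) {
  stopifnot(inherits(params, "utility_params"), n >= 0)
  pf <- beta_from_moments(params$pf_mean, params$pf_sd)
  dis <- beta_from_moments(params$dis_mean, params$dis_sd)
  u_pf <- rbeta(n, pf["alpha"], pf["beta"])
  u_dis <- rbeta(n, dis["alpha"], dis["beta"])
  data.frame(u_pf = u_pf, u_prog = pmax(u_pf - u_dis, 0))
}

# Day on which the progressed state begins (Inf = never progressed while
# observed). Vectorised over patients.
progression_start <- function(second_line_end, third_line_start,
                              followup_end, event,
                              six_months = 182.62) {
  if (is.null(third_line_start)) third_line_start <- rep(NA_real_,
                                                         length(followup_end))
  ps <- ifelse(!is.na(third_line_start),
               third_line_start,
               ifelse(event == 1,
                      pmax(second_line_end, followup_end - six_months),
                      Inf))
  pmin(ps, followup_end)
}

#' Partition a patient's observed survival into health states
#'
#' Two states: progression-free and progressed. The progressed state
#' begins at the start of third-line treatment when one is observed;
#' otherwise, for a patient who died, at 6 months (182.62 days) before
#' death but never before the end of second-line treatment - so a patient
#' surviving less than 6 months is in the progressed state from the end of
#' second-line treatment. A patient alive at censoring or the horizon with
#' no third line remains progression-free throughout.
#'
#' @param second_line_end end of second-line treatment (days from index).
#' @param third_line_start start of third-line treatment (days), or `NA`.
#' @param followup_end end of observed follow-up (days).
#' @param event 1 if follow-up ended in death, 0 if censored.
#' @return data frame of contiguous segments with columns `start`, `end`
#'   (days, half-open) and `state` (`"progression_free"`/`"progressed"`),
#'   covering `[0, followup_end)`.
#' @examples
#' # death at day 400, second line ended day 200, no third line:
#' partition_health_states(200, NA, 400, 1) # progressed from day 217.38
#' @export
partition_health_states <- function(second_line_end, third_line_start,
                                    followup_end, event) {
  stopifnot(length(followup_end) == 1, followup_end >= 0,
            second_line_end >= 0)
  if (second_line_end > followup_end + 1e-9) {
    stop("second_line_end after followup_end")
  }
  if (!is.na(third_line_start) &&
      (third_line_start < 0 || third_line_start > followup_end + 1e-9)) {
    stop("third_line_start outside [0, followup_end]")
  }
  ps <- progression_start(second_line_end, third_line_start,
                          followup_end, event)
  if (ps >= followup_end) {
    seg <- data.frame(start = 0, end = followup_end,
                      state = "progression_free")
  } else if (ps <= 0) {
    seg <- data.frame(start = 0, end = followup_end, state = "progressed")
  } else {
    seg <- data.frame(start = c(0, ps), end = c(ps, followup_end),
                      state = c("progression_free", "progressed"))
  }
  seg$state <- as.character(seg$state)
  seg
}

#' QALYs from a health-state timeline and per-interval life-years
#'
#' Multiplies each 30-day interval's (adjusted, discounted) life-years by
#' the utility of the state occupying the interval; when a progression
#' boundary falls inside an interval the utility is the time-weighted
#' average over the occupied days. Utilities in [0, 1] guarantee
#' `0 <= QALY <= LY`.
#'
#' @param timeline segment data frame from [partition_health_states()].
#' @param u_pf,u_prog utilities of the progression-free and progressed
#'   states.
#' @param ly_intervals per-interval life-years (already IPCW-adjusted and
#'   discounted as required), one entry per grid interval.
#' @inheritParams interval_grid
#' @return QALYs (same units as `ly_intervals` totals).
#' @export
qaly_from_timeline <- function(timeline, u_pf, u_prog, ly_intervals,
                               horizon_days = 1826, interval_days = 30) {
  stopifnot(all(c("start", "end", "state") %in% names(timeline)),
            u_pf >= 0, u_pf <= 1, u_prog >= 0, u_prog <= 1)
  iv <- interval_grid(horizon_days, interval_days)
  if (length(ly_intervals) != iv$n) {
    stop("ly_intervals must have one entry per interval (", iv$n, ")")
  }
  fe <- max(timeline$end)
  if (any(ly_intervals > 0 & iv$starts >= fe)) {
    stop("life-years observed in an interval outside the timeline")
  }
  pf_end <- fe
  pr <- timeline$start[timeline$state == "progressed"]
  if (length(pr)) pf_end <- min(pr)
  occ <- pmax(0, pmin(fe, iv$ends) - iv$starts)
  pf_days <- pmax(0, pmin(pf_end, iv$ends) - iv$starts)
  pf_days <- pmin(pf_days, occ)
  w <- ifelse(occ > 0, (pf_days * u_pf + (occ - pf_days) * u_prog) / occ, 0)
  sum(ly_intervals * w)
}
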