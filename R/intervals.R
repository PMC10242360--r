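#' Interval grid over the analysis horizon
#'
#' The follow-up horizon is divided into half-open 30-day intervals
#' `[k*30, (k+1)*30)` measured in days from the index date (day 0 = first
#' dose of second-line therapy). With the default 5-year horizon of 1826
#' days this yields 61 intervals, the last truncated to 26 days.
#'
#' @param horizon_days analysis horizon in days (default 1826 = 5 years).
#' @param interval_days interval width in days (default 30).
#' @return list with `starts`, `ends`, `mids` (days) and `n` intervals.
#' @export
interval_grid <- function(horizon_days = 1826, interval_days = 30) {
  stopifnot(horizon_days > 0, interval_days > 0)
  starts <- seq(0, horizon_days - 1e-9, by = interval_days)
  ends <- pmin(starts + interval_days, horizon_days)
  list(starts = starts, ends = ends, mids = (starts + ends) / 2,
       n = length(starts), interval_days = interval_days,
       horizon_days = horizon_days)
}

#' Partition one patient's follow-up over the interval grid
#'
#' Returns the number of days alive and under follow-up contributed to each
#' interval: the overlap of `[k*30, (k+1)*30)` with `[0, followup_end)`.
#'
#' @param followup_end end of observed follow-up in days from index
#'   (death, censoring, or the horizon, whichever came first).
#' @inheritParams interval_grid
#' @return numeric vector of days, one per interval.
#' @examples
#' partition_followup(45)[1:3]   # 30, 15, 0
#' partition_followup(60)[1:3]   # 30, 30, 0 (half-open boundary)
#' sum(partition_followup(1826)) # 1826
#' @export
partition_followup <- function(followup_end, horizon_days = 1826,
                               interval_days = 30) {
  stopifnot(length(followup_end) == 1, followup_end >= 0)
  if (followup_end > horizon_days) {
    stop("followup_end (", followup_end, ") exceeds the horizon (",
         horizon_days, " days)")
  }
  iv <- interval_grid(horizon_days, interval_days)
  pmax(0, pmin(followup_end, iv$ends) - iv$starts)
}

# Vectorised overlap: n x K matrix of days alive per interval.
overlap_matrix <- function(followup_end, iv) {
  n <- length(followup_end)
  widths <- iv$ends - iv$starts
  m <- outer(followup_end, iv$starts, "-")
  m <- pmin(m, matrix(widths, n, iv$n, byrow = TRUE))
  pmax(m, 0)
}

#' Discount factor at an annual rate
#'
#' Continuous-compounding-free annual discounting: a quantity accruing at
#' `t_days` from index is multiplied by `(1 + rate)^(-t_days/365.25)`.
#'
#' @param t_days time of accrual in days from index.
#' @param rate annual discount rate (e.g. 0.015 for 1.5%); must be >= 0.
#' @return numeric vector of discount factors.
#' @examples
#' discount_factor(365.25, 0.015) # 1/1.015
#' @export
discount_factor <- function(t_days, rate) {
  if (rate < 0) stop("discount rate must be nonnegative")
  (1 + rate)^(-t_days / 365.25)
}

#' Discount per-interval contributions at interval midpoints
#'
#' Each interval's contribution is multiplied by the discount factor at the
#' interval midpoint (day `k*30 + 15`; the truncated last interval uses its
#' own midpoint).
#'
#' @param contrib numeric vector of per-interval contributions (length =
#'   number of intervals on the grid).
#' @inheritParams discount_factor
#' @inheritParams interval_grid
#' @return discounted contributions, same length as `contrib`.
#' @export
discount_contributions <- function(contrib, rate, horizon_days = 1826,
                                   interval_days = 30) {
  iv <- interval_grid(horizon_days, interval_days)
  if (length(contrib) != iv$n) {
    stop("contrib must have one entry per interval (", iv$n, ")")
  }
  contrib * discount_factor(iv$mids, rate)
}
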