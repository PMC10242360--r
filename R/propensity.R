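#' Default propensity-model covariates
#'
#' Comorbidity (Charlson class, morbidity score), age, urban residence,
#' months from diagnosis to start of second-line therapy, and prior
#' radiation: the covariates of the treatment-assignment model. Further
#' baseline variables are used as balance diagnostics only.
#'
#' @return character vector of cohort column names.
#' @export
default_propensity_covariates <- function() {
  c("age", "urban", "morbidity", "charlson_1plus",
    "months_dx_to_2l", "prior_radiation")
}

#' Fit the propensity-score model
#'
#' Maximum-likelihood logistic regression of treatment on baseline
#' covariates. Constant (degenerate) covariates are dropped with a
#' warning; (quasi-)perfect separation raises an error advising covariate
#' revision, since the resulting weights would be unusable.
#'
#' @param cohort cohort data frame (must contain `arm` and the covariates).
#' @param covariates character vector of covariate column names.
#' @return object of class `propensity_fit`: list with `model` (the glm),
#'   `scores` (per-patient propensity in (0,1)), `covariates`,
#'   `coefficients`.
#' @export
fit_propensity <- function(cohort,
                           covariates = default_propensity_covariates()) {
  stopifnot(is.data.frame(cohort), length(covariates) >= 1)
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) {
    stop("covariate(s) missing from cohort: ", paste(miss, collapse = ", "))
  }
  if (!all(c("control", "treated") %in% cohort$arm)) {
    stop("both arms must be present to fit a propensity model")
  }
  keep <- covariates[vapply(covariates, function(v) {
    x <- cohort[[v]]
    length(unique(x[!is.na(x)])) > 1
  }, logical(1))]
  dropped <- setdiff(covariates, keep)
  if (length(dropped)) {
    warning("dropping constant covariate(s): ", paste(dropped, collapse = ", "))
  }
  if (!length(keep)) stop("no non-degenerate covariates left")
  dat <- cohort[, keep, drop = FALSE]
  dat$.treated <- as.integer(cohort$arm == "treated")
  fml <- stats::as.formula(paste(".treated ~", paste(keep, collapse = " + ")))
  fit <- suppressWarnings(glm(fml, family = binomial(), data = dat))
  scores <- fitted(fit)
  eps <- 1e-8
  if (any(scores < eps) || any(scores > 1 - eps)) {
    stop("(quasi-)perfect separation in the propensity model: fitted ",
         "probabilities at 0/1; revise the covariate set")
  }
  structure(list(model = fit, scores = as.numeric(scores),
                 covariates = keep, coefficients = coef(fit),
                 dropped = dropped),
            class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("Propensity model (logistic):", length(x$scores), "patients\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Inverse probability of treatment weights
#'
#' ATE weights are `1/e` for treated and `1/(1-e)` for controls, where `e`
#' is the propensity score; ATT weights are 1 for treated and `e/(1-e)`
#' for controls. Stabilization multiplies by the marginal arm prevalence.
#' Optional truncation clips weights at quantiles of their distribution.
#' The weighted group sizes (sums of weights per arm) are reported to one
#' decimal place by the print method, as in a weighted baseline table.
#'
#' @param fit a [fit_propensity()] object.
#' @param cohort the cohort the model was fitted on (for arm labels).
#' @param estimand `"ATE"` (default) or `"ATT"`.
#' @param stabilized multiply by marginal arm prevalence?
#' @param truncate optional two-sided quantile level, e.g. `0.01` clips
#'   weights at their 1st and 99th percentiles; `NULL` = no truncation.
#' @return numeric weight vector of class `iptw` with attributes
#'   `estimand`, `stabilized`, `weighted_n` (named per-arm sums).
#' @export
iptw_weights <- function(fit, cohort, estimand = c("ATE", "ATT"),
                         stabilized = FALSE, truncate = NULL) {
  estimand <- match.arg(estimand)
  stopifnot(inherits(fit, "propensity_fit"),
            nrow(cohort) == length(fit$scores))
  e <- fit$scores
  treated <- cohort$arm == "treated"
  w <- if (estimand == "ATE") {
    ifelse(treated, 1 / e, 1 / (1 - e))
  } else {
    ifelse(treated, 1, e / (1 - e))
  }
  if (stabilized) {
    p <- mean(treated)
    w <- w * ifelse(treated, p, 1 - p)
  }
  if (!is.null(truncate)) {
    stopifnot(truncate > 0, truncate < 0.5)
    lims <- quantile(w, c(truncate, 1 - truncate))
    w <- pmin(pmax(w, lims[1]), lims[2])
  }
  wn <- c(control = sum(w[!treated]), treated = sum(w[treated]))
  structure(w, estimand = estimand, stabilized = stabilized,
            weighted_n = wn, class = "iptw")
}

#' @export
print.iptw <- function(x, ...) {
  wn <- attr(x, "weighted_n")
  cat("IPTW weights (", attr(x, "estimand"),
      if (attr(x, "stabilized")) ", stabilized", "): ",
      length(x), " patients\n", sep = "")
  cat(sprintf("  weighted N: control %.1f, treated %.1f\n", wn[1], wn[2]))
  invisible(x)
}

weighted_mean_sd <- function(x, w) {
  m <- sum(w * x) / sum(w)
  v <- sum(w * (x - m)^2) / sum(w) # population (frequency-weight) formula
  c(mean = m, sd = sqrt(v))
}

#' Weighted standardized difference between two groups
#'
#' Continuous covariates: `(m1 - m0) / sqrt((s1^2 + s0^2)/2)` with
#' (weighted) means and population-formula SDs. Binary covariates:
#' `(p1 - p0) / sqrt((p1(1-p1) + p0(1-p0))/2)` with (weighted)
#' proportions. Signed; antisymmetric under group swap; invariant to
#' affine rescaling of a continuous covariate. `|d| < 0.1` conventionally
#' indicates adequate balance.
#'
#' @param x1,x0 covariate values in the two groups (binary covariates may
#'   be logical or 0/1).
#' @param w1,w0 optional nonnegative weights (default: unweighted).
#' @param binary treat the covariate as binary? Default: autodetect
#'   (logical, or numeric with values in {0, 1}).
#' @return signed standardized difference.
#' @seealso [std_diff_moments()], [std_diff_props()] for computing the
#'   same quantity from published summary statistics.
#' @export
standardized_difference <- function(x1, x0, w1 = NULL, w0 = NULL,
                                    binary = NULL) {
  if (is.null(w1)) w1 <- rep(1, length(x1))
  if (is.null(w0)) w0 <- rep(1, length(x0))
  stopifnot(length(w1) == length(x1), length(w0) == length(x0),
            all(w1 >= 0), all(w0 >= 0))
  x1 <- as.numeric(x1); x0 <- as.numeric(x0)
  if (is.null(binary)) {
    binary <- all(c(x1, x0) %in% c(0, 1))
  }
  if (binary) {
    p1 <- sum(w1 * x1) / sum(w1)
    p0 <- sum(w0 * x0) / sum(w0)
    std_diff_props(p1, p0)
  } else {
    ms1 <- weighted_mean_sd(x1, w1)
    ms0 <- weighted_mean_sd(x0, w0)
    std_diff_moments(ms1["mean"], ms1["sd"], ms0["mean"], ms0["sd"])
  }
}

#' Standardized difference from published means and SDs
#'
#' @param m1,s1 mean and SD in group 1.
#' @param m0,s0 mean and SD in group 0.
#' @return signed standardized difference `(m1 - m0)/sqrt((s1^2+s0^2)/2)`.
#' @examples
#' round(abs(std_diff_moments(57.5, 18.5, 59.5, 17.9)), 2) # 0.11
#' @export
std_diff_moments <- function(m1, s1, m0, s0) {
  pooled <- sqrt((s1^2 + s0^2) / 2)
  if (pooled == 0) {
    if (isTRUE(all.equal(m1, m0))) return(0)
    stop("zero pooled variance with unequal means: standardized ",
         "difference undefined")
  }
  unname((m1 - m0) / pooled)
}

#' Standardized difference from two proportions
#'
#' @param p1,p0 proportions in the two groups.
#' @return signed standardized difference
#'   `(p1 - p0)/sqrt((p1(1-p1)+p0(1-p0))/2)`.
#' @examples
#' round(abs(std_diff_props(0.6663, 0.6771)), 2) # 0.02
#' @export
std_diff_props <- function(p1, p0) {
  stopifnot(p1 >= 0, p1 <= 1, p0 >= 0, p0 <= 1)
  pooled <- sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
  if (pooled == 0) {
    if (isTRUE(all.equal(p1, p0))) return(0)
    stop("zero pooled variance with unequal proportions")
  }
  (p1 - p0) / pooled
}

#' Weighted covariate balance table
#'
#' One row per covariate (factor covariates are expanded to one indicator
#' row per level) with the weighted standardized difference between arms
#' and a balance flag at the conventional |d| < 0.1 threshold. With unit
#' weights this reduces to the unweighted standardized differences.
#'
#' @param cohort cohort data frame.
#' @param weights optional weight vector (e.g. from [iptw_weights()]);
#'   default unit weights.
#' @param covariates covariate columns to tabulate.
#' @return data frame of class `balance_table`: columns `covariate`,
#'   `type`, `control`, `treated` (weighted mean or proportion),
#'   `std_diff` (signed), `abs_std_diff` (rounded to 2 decimals),
#'   `balanced` (|d| < 0.1 on the unrounded value). Attribute
#'   `weighted_n`: per-arm weighted sizes.
#' @export
balance_table <- function(cohort, weights = NULL,
                          covariates = default_propensity_covariates()) {
  stopifnot(is.data.frame(cohort))
  if (is.null(weights)) weights <- rep(1, nrow(cohort))
  stopifnot(length(weights) == nrow(cohort))
  treated <- cohort$arm == "treated"
  rows <- list()
  for (v in covariates) {
    x <- cohort[[v]]
    if (is.null(x)) stop("covariate missing from cohort: ", v)
    if (is.factor(x) || is.character(x)) {
      for (lev in sort(unique(as.character(x)))) {
        ind <- as.numeric(as.character(x) == lev)
        rows[[paste0(v, ":", lev)]] <- c(
          type = "binary",
          stats = list(balance_row(ind, treated, weights, binary = TRUE)))
      }
    } else {
      bin <- is.logical(x) || all(x[!is.na(x)] %in% c(0, 1))
      rows[[v]] <- c(type = if (bin) "binary" else "continuous",
                     stats = list(balance_row(as.numeric(x), treated,
                                              weights, binary = bin)))
    }
  }
  out <- data.frame(
    covariate = names(rows),
    type = vapply(rows, `[[`, "", "type"),
    control = vapply(rows, function(r) r$stats["control"], 0),
    treated = vapply(rows, function(r) r$stats["treated"], 0),
    std_diff = vapply(rows, function(r) r$stats["std_diff"], 0),
    row.names = NULL, stringsAsFactors = FALSE)
  out$abs_std_diff <- round(abs(out$std_diff), 2)
  out$balanced <- abs(out$std_diff) < 0.1
  structure(out,
            weighted_n = c(control = sum(weights[!treated]),
                           treated = sum(weights[treated])),
            class = c("balance_table", "data.frame"))
}

balance_row <- function(x, treated, weights, binary) {
  w1 <- weights[treated]; w0 <- weights[!treated]
  x1 <- x[treated]; x0 <- x[!treated]
  d <- standardized_difference(x1, x0, w1, w0, binary = binary)
  c(control = sum(w0 * x0) / sum(w0),
    treated = sum(w1 * x1) / sum(w1),
    std_diff = d)
}

#' @export
print.balance_table <- function(x, digits = 3, ...) {
  wn <- attr(x, "weighted_n")
  cat(sprintf("Covariate balance (weighted N: control %.1f, treated %.1f)\n",
              wn[1], wn[2]))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
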