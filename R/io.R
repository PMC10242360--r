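#' Read and validate a cohort CSV
#'
#' Expected columns: `patient_id` (unique), `arm`
#' (`"control"`/`"treated"`), `followup_end`, `event` (1 death /
#' 0 censored), `second_line_end`, optional `third_line_start` (empty =
#' none), plus any baseline covariate columns. Times are days from the
#' index date. Row-level problems are aggregated and reported with row
#' numbers.
#'
#' @param path CSV file path.
#' @return validated cohort data frame of class `cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("cohort file is empty: ", path)
  req <- c("patient_id", "arm", "followup_end", "event", "second_line_end")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("cohort file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"third_line_start" %in% names(df)) df$third_line_start <- NA_real_
  probs <- character(0)
  note <- function(rows, what) {
    if (length(rows)) {
      probs <<- c(probs, paste0(what, " (rows ",
                                paste(head(rows, 5), collapse = ", "),
                                if (length(rows) > 5) ", ..." , ")"))
    }
  }
  note(which(duplicated(df$patient_id)), "duplicate patient_id")
  note(which(!df$arm %in% c("control", "treated")), "unknown arm label")
  note(which(!df$event %in% c(0, 1)), "event not 0/1")
  note(which(df$followup_end < 0 | df$second_line_end < 0),
       "negative time")
  note(which(df$second_line_end > df$followup_end + 1e-9),
       "second_line_end after death/censoring")
  tl <- df$third_line_start
  note(which(!is.na(tl) & (tl < 0 | tl > df$followup_end + 1e-9)),
       "third_line_start outside follow-up")
  if (length(probs)) {
    stop("cohort validation failed:\n  - ", paste(probs, collapse = "\n  - "))
  }
  class(df) <- c("cohort", "data.frame")
  df
}

#' Read and validate a cost-ledger CSV
#'
#' Expected columns: `patient_id`, `interval` (0-based 30-day index),
#' `category`, `amount` (CAD), optional `drug_of_interest` (logical).
#' When a cohort is supplied, entries must reference known patients and
#' lie within their observed follow-up.
#'
#' @param path CSV file path.
#' @param cohort optional cohort for cross-validation.
#' @return validated ledger data frame of class `cost_ledger`.
#' @export
read_cost_ledger <- function(path, cohort = NULL) {
  if (!file.exists(path)) stop("ledger file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "interval", "category", "amount")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("ledger file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"drug_of_interest" %in% names(df)) df$drug_of_interest <- FALSE
  df$drug_of_interest <- as.logical(df$drug_of_interest)
  if (any(df$interval < 0) || any(df$interval != floor(df$interval))) {
    stop("ledger interval indices must be nonnegative integers")
  }
  if (!is.numeric(df$amount) || anyNA(df$amount)) {
    stop("ledger amounts must be numeric and non-missing")
  }
  if (!is.null(cohort)) {
    pid <- match(df$patient_id, cohort$patient_id)
    if (anyNA(pid)) {
      stop("ledger references patient_id absent from cohort: ",
           paste(unique(head(df$patient_id[is.na(pid)])), collapse = ", "))
    }
    beyond <- df$interval * 30 >= cohort$followup_end[pid]
    if (any(beyond)) {
      stop("ledger entries beyond observed follow-up for patient(s): ",
           paste(unique(head(df$patient_id[beyond])), collapse = ", "))
    }
  }
  class(df) <- c("cost_ledger", "data.frame")
  df
}

#' Write cohort / ledger CSVs
#'
#' Plain CSV writers for the documented cohort and cost-ledger schemas.
#'
#' @param x cohort or ledger data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
write_cost_ledger <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles every analysis option: either paths to cohort/ledger CSVs or a
#' [sim_config()] to simulate from, the interval grid, the discount rate,
#' utility parameters, bootstrap size, willingness-to-pay settings and the
#' output directory.
#'
#' @param cohort_path,ledger_path input CSVs (analyze mode), or `NULL`.
#' @param simulate a [sim_config()] (simulate mode), or `NULL`.
#' @param horizon_days,interval_days analysis grid (1826 / 30).
#' @param discount_rate annual discount rate (0.015).
#' @param utility_params a [utility_params()] list.
#' @param B bootstrap replicates (default 1000).
#' @param seed RNG seed for the whole run.
#' @param wtp_grid willingness-to-pay grid for the CEAC.
#' @param nmb_thresholds thresholds at which NMB regressions are reported.
#' @param covariates propensity-model covariates.
#' @param estimand,stabilized,truncate IPTW options (see
#'   [iptw_weights()]).
#' @param include_partial censored-interval convention (see
#'   [ipcw_adjust()]).
#' @param sens_rates discount rates for the sensitivity table.
#' @param price_fractions drug price-reduction fractions.
#' @param output_dir directory for report artifacts, or `NULL` to skip
#'   writing.
#' @param plots write PNG figures?
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort_path = NULL, ledger_path = NULL,
                       simulate = NULL,
                       horizon_days = 1826, interval_days = 30,
                       discount_rate = 0.015,
                       utility_params = rwcea::utility_params(),
                       B = 1000, seed = 1L,
                       wtp_grid = seq(0, 300000, by = 1000),
                       nmb_thresholds = c(50000, 100000, 150000),
                       covariates = default_propensity_covariates(),
                       estimand = "ATE", stabilized = FALSE,
                       truncate = NULL, include_partial = FALSE,
                       sens_rates = c(0, 0.015, 0.03),
                       price_fractions = seq(0, 1, by = 0.1),
                       output_dir = NULL, plots = TRUE) {
  if (is.null(simulate)) {
    if (is.null(cohort_path) || is.null(ledger_path)) {
      stop("either supply cohort_path and ledger_path or a sim_config ",
           "via `simulate`")
    }
    if (!file.exists(cohort_path)) stop("cohort_path does not exist: ",
                                        cohort_path)
    if (!file.exists(ledger_path)) stop("ledger_path does not exist: ",
                                        ledger_path)
  } else {
    stopifnot(inherits(simulate, "sim_config"))
  }
  structure(list(cohort_path = cohort_path, ledger_path = ledger_path,
                 simulate = simulate, horizon_days = horizon_days,
                 interval_days = interval_days,
                 discount_rate = discount_rate,
                 utility_params = utility_params, B = B, seed = seed,
                 wtp_grid = wtp_grid, nmb_thresholds = nmb_thresholds,
                 covariates = covariates, estimand = estimand,
                 stabilized = stabilized, truncate = truncate,
                 include_partial = include_partial,
                 sens_rates = sens_rates,
                 price_fractions = price_fractions,
                 output_dir = output_dir, plots = plots),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose keys mirror the [run_config()] arguments; a
#' `simulate:` mapping is passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  if (!is.null(y$utility_params)) {
    y$utility_params <- do.call(utility_params, y$utility_params)
  }
  do.call(run_config, y)
}

# stable short hash of the configuration (polynomial rolling hash over its
# deparse, in double arithmetic to stay inside 2^31)
config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "output_dir")]),
             collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full cost-effectiveness pipeline
#'
#' Simulates or reads the cohort and cost ledger, fits the propensity
#' model, computes IPTW weights and the balance table, runs the
#' partitioned IPCW adjustment, the weighted incremental summary, the
#' bootstrap with CE-plane quadrants and CEAC, net-benefit regressions at
#' the configured thresholds, and the discount-rate and price-reduction
#' sensitivity analyses. When `output_dir` is set, writes CSV tables, PNG
#' figures and a JSON sidecar with the seed, options and a config hash.
#' Deterministic given `seed`.
#'
#' @param config a [run_config()].
#' @return list of class `cea_report` with components `cohort`, `ledger`,
#'   `propensity`, `weights`, `balance`, `adjusted`, `summary`,
#'   `bootstrap`, `ceac`, `nmb`, `discount_sens`, `price_curve`,
#'   `meta`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- NULL # the pipeline seed governs
    cohort <- simulate_cohort(sim)
    ledger <- simulate_cost_ledger(cohort, sim)
  } else {
    cohort <- read_cohort(config$cohort_path)
    ledger <- read_cost_ledger(config$ledger_path, cohort)
  }

  fit <- fit_propensity(cohort, config$covariates)
  w <- iptw_weights(fit, cohort, estimand = config$estimand,
                    stabilized = config$stabilized,
                    truncate = config$truncate)
  bal_covs <- intersect(
    unique(c(config$covariates, "age", "sex_male", "income_quintile",
             "urban", "morbidity", "adg_count", "charlson_1plus",
             "prior_radiation", "prior_resection", "firstline",
             "months_dx_to_2l")),
    names(cohort))
  bal <- balance_table(cohort, w, bal_covs)

  adj <- adjusted_outcomes(cohort, ledger,
                           discount_rate = config$discount_rate,
                           utility_params = config$utility_params,
                           include_partial = config$include_partial,
                           horizon_days = config$horizon_days,
                           interval_days = config$interval_days)
  summ <- incremental_summary(adj, w)

  boot <- bootstrap_cea(cohort, ledger, B = config$B, seed = config$seed,
                        discount_rate = config$discount_rate,
                        covariates = config$covariates,
                        utility_params = config$utility_params,
                        include_partial = config$include_partial,
                        horizon_days = config$horizon_days,
                        interval_days = config$interval_days)
  cc <- ceac(boot, wtp = config$wtp_grid, measure = "ly")
  nmb <- do.call(rbind, lapply(config$nmb_thresholds, function(l) {
    r <- nmb_regression(adj, w, lambda = l, measure = "ly")
    data.frame(lambda = l, inmb = r$estimate, lo = r$ci[1], hi = r$ci[2],
               cost_effective = r$cost_effective)
  }))
  sens <- discount_sensitivity(cohort, ledger, rates = config$sens_rates,
                               weights = w,
                               covariates = config$covariates,
                               utility_params = config$utility_params,
                               include_partial = config$include_partial,
                               horizon_days = config$horizon_days,
                               interval_days = config$interval_days)
  price <- price_reduction_curve(cohort, ledger,
                                 fractions = config$price_fractions,
                                 weights = w,
                                 discount_rate = config$discount_rate,
                                 utility_params = config$utility_params,
                                 covariates = config$covariates,
                                 include_partial = config$include_partial,
                                 horizon_days = config$horizon_days,
                                 interval_days = config$interval_days)

  meta <- list(seed = config$seed, B = config$B,
               discount_rate = config$discount_rate,
               estimand = config$estimand, stabilized = config$stabilized,
               include_partial = config$include_partial,
               horizon_days = config$horizon_days,
               interval_days = config$interval_days,
               config_hash = config_hash(config),
               n_control = sum(cohort$arm == "control"),
               n_treated = sum(cohort$arm == "treated"),
               timestamp = format(Sys.time(), tz = "UTC"))

  report <- structure(list(cohort = cohort, ledger = ledger,
                           propensity = fit, weights = w, balance = bal,
                           adjusted = adj, summary = summ,
                           bootstrap = boot, ceac = cc, nmb = nmb,
                           discount_sens = sens, price_curve = price,
                           meta = meta),
                      class = "cea_report")
  if (!is.null(config$output_dir)) {
    write_report(report, config$output_dir, plots = config$plots)
  }
  report
}

write_report <- function(report, dir, plots = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_cohort(report$cohort, p("cohort.csv"))
  write_cost_ledger(report$ledger, p("cost_ledger.csv"))
  write.csv(as.data.frame(report$balance), p("balance_table.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(report$adjusted), p("adjusted_outcomes.csv"),
            row.names = FALSE)
  write.csv(report$summary$table, p("incremental_summary.csv"),
            row.names = FALSE)
  write.csv(report$bootstrap$replicates, p("bootstrap_replicates.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(report$ceac), p("ceac.csv"), row.names = FALSE)
  write.csv(report$nmb, p("nmb_table.csv"), row.names = FALSE)
  write.csv(report$discount_sens, p("discount_sensitivity.csv"),
            row.names = FALSE)
  write.csv(report$price_curve, p("price_reduction.csv"),
            row.names = FALSE)
  jsonlite::write_json(report$meta, p("run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (plots) {
    ggplot2::ggsave(p("ce_plane.png"), plot_ce_plane(report$bootstrap),
                    width = 6, height = 5, dpi = 150)
    ggplot2::ggsave(p("ceac.png"), plot_ceac(report$ceac),
                    width = 6, height = 4, dpi = 150)
    ggplot2::ggsave(p("price_reduction.png"),
                    plot_price_curve(report$price_curve),
                    width = 6, height = 4, dpi = 150)
  }
  invisible(dir)
}

#' @export
print.cea_report <- function(x, ...) {
  cat("CEA report (seed", x$meta$seed, ", B =", x$meta$B, ")\n\n")
  print(x$summary)
  cat("\n")
  print(x$bootstrap)
  invisible(x)
}
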