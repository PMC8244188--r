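# Flat-file interface: one CSV holds per-patient time-to-first-event
# records for many (trial, arm, AE type) units. Columns: trial_id, arm,
# ae_type, time_days, outcome_code with integer codes 0 = censored,
# 1 = AE, 2 = death before AE, 3 = other competing event. This is the
# sponsor-agnostic mapping of an ADAE/ADSL-style export: one row per
# patient per analysed AE type, carrying time to first event and its type.

required_columns <- c("trial_id", "arm", "ae_type", "time_days",
                      "outcome_code")

#' Read analysis sets from a flat CSV file
#'
#' Validates every row (positive finite time, known outcome code) and
#' reports violations with their line numbers, then groups rows into one
#' [analysis_set()] per (trial, arm, AE type) unit.
#'
#' @param path Path to a CSV file with header columns `trial_id`, `arm`,
#'   `ae_type`, `time_days`, `outcome_code`.
#' @return Named list of [analysis_set()] objects, keyed
#'   `trial/arm/ae_type`.
#' @export
read_analysis_sets <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_columns, names(df))
  if (length(missing) > 0L)
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_time <- !is.numeric(df$time_days) | is.na(df$time_days) |
    df$time_days <= 0 | !is.finite(df$time_days)
  bad_code <- !df$outcome_code %in% 0:3
  if (any(bad_time | bad_code)) {
    msgs <- c(
      if (any(bad_time))
        paste0("non-positive or missing time_days at line(s) ",
               paste(line[bad_time], collapse = ", ")),
      if (any(bad_code))
        paste0("unknown outcome_code at line(s) ",
               paste(line[bad_code], collapse = ", ")))
    stop(paste(msgs, collapse = "; "), call. = FALSE)
  }
  key <- paste(df$trial_id, df$arm, df$ae_type, sep = "/")
  out <- lapply(split(df, key), function(d)
    analysis_set(d$time_days, as.integer(d$outcome_code),
                 trial_id = d$trial_id[1], arm = d$arm[1],
                 ae_type = d$ae_type[1]))
  out[unique(key)]
}

#' Write analysis sets to a flat CSV file
#'
#' Inverse of [read_analysis_sets()]; the round trip is lossless for all
#' record fields.
#'
#' @param sets A list of [analysis_set()] objects (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_analysis_sets <- function(sets, path) {
  if (inherits(sets, "analysis_set")) sets <- list(sets)
  rows <- lapply(sets, function(s)
    data.frame(trial_id = s$trial_id, arm = s$arm, ae_type = s$ae_type,
               time_days = s$data$time,
               outcome_code = match(s$data$outcome, outcome_levels) - 1L,
               row.names = NULL))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Run the full comparison pipeline
#'
#' Executes the whole study design on a collection of analysis sets (or a
#' freshly simulated portfolio): per-unit estimates for all estimators
#' and tau rules, ratio records with bootstrap standard errors, frequency
#' category cross-tabulations against the gold standard, random-effects
#' meta-analysis and meta-regression per estimator, the event-frequency
#' summary, and the composite-endpoint censoring check. All outputs are
#' plain CSV/JSON under `outdir`, plus a manifest recording the seed and
#' exclusion counts.
#'
#' @param sets List of [analysis_set()] objects; if `NULL`, a portfolio is
#'   simulated with [simulate_portfolio()] using `portfolio_args`.
#' @param outdir Output directory (created if needed).
#' @param tau_rules Character/numeric vector of tau rules for the
#'   estimate table (`"max"` or quantiles); ratios and meta use the first.
#' @param B Bootstrap replicates per unit.
#' @param seed Integer master seed for simulation and bootstrap.
#' @param portfolio_args List of arguments for [simulate_portfolio()].
#' @return Invisible list with `estimates`, `ratios`, `meta`,
#'   `meta_regression`, `crosstabs`, `event_frequencies`, `composite`,
#'   `truth` (when simulated) and `manifest`.
#' @export
run_pipeline <- function(sets = NULL, outdir, tau_rules = "max",
                         B = 200, seed = 1L, portfolio_args = list()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  if (is.null(sets)) {
    pf <- do.call(simulate_portfolio, c(portfolio_args, list(seed = seed)))
    sets <- pf$sets
    truth <- pf$truth
    write_analysis_sets(sets, file.path(outdir, "portfolio.csv"))
    utils::write.csv(truth, file.path(outdir, "truth.csv"),
                     row.names = FALSE)
  }
  meta_cols <- function(s) data.frame(trial_id = s$trial_id, arm = s$arm,
                                      ae_type = s$ae_type,
                                      row.names = NULL)

  estimates <- do.call(rbind, lapply(sets, function(s) {
    do.call(rbind, lapply(tau_rules, function(r) {
      tau <- evaluation_time(s, r)
      cbind(meta_cols(s), tau_rule = as.character(r),
            estimate_all(s, tau))
    }))
  }))
  rownames(estimates) <- NULL
  utils::write.csv(estimates, file.path(outdir, "estimates.csv"),
                   row.names = FALSE)

  freq <- do.call(rbind, lapply(sets, function(s) {
    tau <- evaluation_time(s, tau_rules[[1]])
    cnt <- count_events(s, tau)
    cbind(meta_cols(s),
          data.frame(n = cnt$n, prop_ae = cnt$proportions[["ae"]],
                     prop_death = cnt$proportions[["death_before_ae"]],
                     prop_other_ce = cnt$proportions[["other_ce"]],
                     prop_censored = cnt$proportions[["censored"]],
                     row.names = NULL))
  }))
  rownames(freq) <- NULL
  utils::write.csv(freq, file.path(outdir, "event_frequencies.csv"),
                   row.names = FALSE)

  composite <- do.call(rbind, lapply(sets, function(s) {
    tau <- evaluation_time(s, tau_rules[[1]])
    cmp <- composite_endpoint_analysis(s, tau)
    cbind(meta_cols(s),
          data.frame(ip_composite = cmp$ip_composite,
                     one_minus_km_composite = cmp$one_minus_km_composite,
                     ratio = cmp$ratio, row.names = NULL))
  }))
  rownames(composite) <- NULL
  utils::write.csv(composite, file.path(outdir, "composite_endpoint.csv"),
                   row.names = FALSE)

  ratios <- compare_units(sets, tau_rule = tau_rules[[1]], B = B,
                          seed = seed)
  utils::write.csv(ratios, file.path(outdir, "ratios.csv"),
                   row.names = FALSE)

  est_wide <- split(ratios, ratios$estimator)
  gold <- est_wide[[1]]$gold
  crosstabs <- lapply(est_wide, function(d)
    category_crosstab(d$gold, d$estimate, name = d$estimator[1]))
  ct_rows <- do.call(rbind, lapply(crosstabs, function(tab) {
    df <- as.data.frame(tab)
    df$comparator_estimator <- attr(tab, "comparator")
    df
  }))
  rownames(ct_rows) <- NULL
  utils::write.csv(ct_rows, file.path(outdir, "category_crosstabs.csv"),
                   row.names = FALSE)

  meta <- meta_by_estimator(ratios)
  mreg <- lapply(est_wide, function(d) {
    ok <- !d$excluded
    if (sum(ok) < 5L) return(NULL)
    fit <- meta_regression(d[ok, ], multivariable = TRUE)
    data.frame(estimator = d$estimator[1],
               average_ratio = fit$average_ratio,
               fit$coefficients, row.names = NULL)
  })
  mreg <- do.call(rbind, mreg[!vapply(mreg, is.null, logical(1))])
  rownames(mreg) <- NULL
  utils::write.csv(meta, file.path(outdir, "meta_analysis.csv"),
                   row.names = FALSE)
  if (!is.null(mreg))
    utils::write.csv(mreg, file.path(outdir, "meta_regression.csv"),
                     row.names = FALSE)

  manifest <- list(
    seed = seed,
    n_units = length(sets),
    tau_rules = as.character(tau_rules),
    bootstrap_replicates = B,
    package_version = as.character(utils::packageVersion("aerisk")),
    excluded_ratio_rows = sum(ratios$excluded),
    exclusion_reasons = as.list(table(ratios$reason[ratios$excluded])),
    total_degenerate_bootstrap = sum(ratios$n_degenerate, na.rm = TRUE))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(estimates = estimates, ratios = ratios, meta = meta,
                 meta_regression = mreg, crosstabs = crosstabs,
                 event_frequencies = freq, composite = composite,
                 truth = truth, manifest = manifest))
}
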