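# Per-unit comparison of estimators against the gold-standard
# Aalen-Johansen: point ratios, bootstrap standard errors of log-ratios,
# unit covariate summaries, and the composite-endpoint check that isolates
# the effect of censoring.

#' Ratio of an estimate to the gold standard
#'
#' Ratios are analysed on the log scale; a unit is flagged undefined (and
#' later excluded from meta-analysis) when either the comparator estimate
#' or the gold-standard estimate is zero, so a log of zero is never taken.
#'
#' @param est Comparator point estimate.
#' @param gold Gold-standard (Aalen-Johansen, all-CE) point estimate on
#'   the same analysis set and at the same `tau`.
#' @return List with `ratio`, `log_ratio` and logical `defined`.
#' @export
ratio_vs_gold <- function(est, gold) {
  stopifnot(is.numeric(est), is.numeric(gold),
            length(est) == 1L, length(gold) == 1L)
  if (est <= 0 || gold <= 0)
    return(list(ratio = NA_real_, log_ratio = NA_real_, defined = FALSE))
  list(ratio = est / gold, log_ratio = log(est / gold), defined = TRUE)
}

resample_set <- function(set, idx) {
  out <- set
  out$data <- set$data[idx, , drop = FALSE]
  out$data$subject_id <- seq_along(idx)
  out
}

#' Bootstrap the log-ratios of all estimators versus the gold standard
#'
#' Nonparametric bootstrap over patients within one analysis set: each
#' replicate resamples the n patients with replacement, re-derives the
#' evaluation time under the active tau rule, and recomputes every
#' comparator estimator together with the gold-standard Aalen-Johansen.
#' The standard error of each log-ratio is the standard deviation of the
#' finite replicate log-ratios; the confidence interval is the 2.5/97.5
#' percentile of the replicate ratios. Replicates where either estimate is
#' zero are degenerate: they are dropped and counted, never imputed.
#'
#' @param set An [analysis_set()].
#' @param tau_rule `"max"` or a quantile in (0, 1]; re-applied within each
#'   replicate so the estimand stays consistent under resampling.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; fixed seed gives bit-identical results.
#' @param estimators Comparator estimators to bootstrap (default all five
#'   non-gold estimators).
#' @return Data frame with one row per estimator: `estimator`,
#'   `se_log_ratio`, `ci_low`, `ci_high` (ratio scale), `n_degenerate`,
#'   `B`.
#' @export
bootstrap_unit_ratios <- function(set, tau_rule = "max", B = 1000,
                                  seed = 1L,
                                  estimators = setdiff(estimator_names(),
                                                       "aje")) {
  stopifnot(inherits(set, "analysis_set"), B >= 2)
  n <- nrow(set$data)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lr <- matrix(NA_real_, nrow = B, ncol = length(estimators),
               dimnames = list(NULL, estimators))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_set <- resample_set(set, idx)
    tau_b <- evaluation_time(rep_set, tau_rule)
    gold_b <- aalen_johansen(rep_set, tau_b)
    if (gold_b <= 0) next
    for (e in estimators) {
      est_b <- estimate_by_name(rep_set, e, tau_b)
      if (est_b > 0) lr[b, e] <- log(est_b / gold_b)
    }
  }
  res <- lapply(estimators, function(e) {
    x <- lr[, e]
    ok <- is.finite(x)
    if (!any(ok))
      stop("all bootstrap replicates degenerate for estimator ", e,
           call. = FALSE)
    ci <- stats::quantile(exp(x[ok]), c(0.025, 0.975), names = FALSE)
    data.frame(estimator = e,
               se_log_ratio = stats::sd(x[ok]),
               ci_low = ci[1], ci_high = ci[2],
               n_degenerate = sum(!ok), B = B)
  })
  do.call(rbind, res)
}

#' Bootstrap standard error of one estimator's log-ratio
#'
#' Single-estimator interface to [bootstrap_unit_ratios()].
#'
#' @inheritParams bootstrap_unit_ratios
#' @param estimator_name One comparator estimator, see [estimator_names()].
#' @return List with `se`, `ci_low`, `ci_high`, `n_degenerate`, `B`.
#' @export
bootstrap_log_ratio_se <- function(set, estimator_name, tau_rule = "max",
                                   B = 1000, seed = 1L) {
  res <- bootstrap_unit_ratios(set, tau_rule, B, seed,
                               estimators = estimator_name)
  list(se = res$se_log_ratio, ci_low = res$ci_low, ci_high = res$ci_high,
       n_degenerate = res$n_degenerate, B = res$B)
}

# set.seed inside package functions must not disturb the caller's RNG
# stream; stash and restore .Random.seed around the bootstrap.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Composite-endpoint check of the censoring effect
#'
#' Merges AE and competing events into one composite event type, which
#' turns the data into a single-endpoint survival setting where one minus
#' Kaplan-Meier is the valid reference. The incidence proportion divided
#' by composite one minus Kaplan-Meier then isolates the downward bias
#' attributable to censoring alone: the ratio is at most 1, and equals 1
#' without censoring before the last event. When the last observed record
#' is an event, composite one minus Kaplan-Meier reaches 1 at the maximum
#' follow-up time.
#'
#' @inheritParams incidence_proportion
#' @return List with `ip_composite`, `one_minus_km_composite` and `ratio`
#'   (`NA` when no composite event is observed by `tau`).
#' @export
composite_endpoint_analysis <- function(set, tau) {
  stopifnot(inherits(set, "analysis_set"))
  check_tau(tau)
  comp <- set
  is_event <- comp$data$outcome != "censored"
  comp$data$outcome <- ifelse(is_event, "ae", "censored")
  ip <- incidence_proportion(comp, tau)
  km <- one_minus_kaplan_meier(comp, tau)
  list(ip_composite = ip,
       one_minus_km_composite = km,
       ratio = if (km > 0) ip / km else NA_real_)
}

#' Unit-level covariates for the meta-regression
#'
#' Summaries of one (trial, AE-type) unit at `tau`: the percentage of
#' censored observations, the percentage of competing events, the
#' evaluation time in years (365.25 days/year), and the gold-standard
#' Aalen-Johansen AE probability.
#'
#' @inheritParams incidence_proportion
#' @return List with `pct_censoring`, `pct_ce`, `tau_years`,
#'   `aje_probability`.
#' @export
summarize_unit <- function(set, tau) {
  cnt <- count_events(set, tau)
  list(pct_censoring = 100 * cnt$n_censored / cnt$n,
       pct_ce = 100 * (cnt$n_death + cnt$n_other_ce) / cnt$n,
       tau_years = tau / 365.25,
       aje_probability = aalen_johansen(set, tau))
}

#' Compare all estimators to the gold standard across many units
#'
#' The workhorse of the comparison stage: for each analysis set it derives
#' the evaluation time under `tau_rule`, computes all estimators, forms
#' ratios against the gold-standard Aalen-Johansen, attaches bootstrap
#' standard errors of the log-ratios, and records the unit covariates.
#' Units (or estimator rows) with a zero gold-standard or comparator
#' estimate are kept in the output but flagged excluded with a reason.
#'
#' @param sets List of [analysis_set()] objects.
#' @param tau_rule `"max"` or a quantile in (0, 1].
#' @param B Bootstrap replicates per unit.
#' @param seed Integer master seed; per-unit seeds are derived from it.
#' @return Data frame with one row per (unit, comparator estimator):
#'   identifiers, `tau`, `estimate`, `gold`, `ratio`, `log_ratio`,
#'   `se_log_ratio`, percentile `ci_low`/`ci_high`, `n_degenerate`,
#'   covariates, and `excluded`/`reason`.
#' @export
compare_units <- function(sets, tau_rule = "max", B = 1000, seed = 1L) {
  if (inherits(sets, "analysis_set")) sets <- list(sets)
  unit_seeds <- derive_seeds(seed, length(sets))
  rows <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    set <- sets[[i]]
    tau <- evaluation_time(set, tau_rule)
    gold <- aalen_johansen(set, tau)
    cov <- summarize_unit(set, tau)
    comparators <- setdiff(estimator_names(), "aje")
    est <- vapply(comparators, estimate_by_name, numeric(1),
                  set = set, tau = tau)
    boot <- tryCatch(
      bootstrap_unit_ratios(set, tau_rule, B, seed = unit_seeds[i],
                            estimators = comparators),
      error = function(e) NULL)
    df <- data.frame(trial_id = set$trial_id, arm = set$arm,
                     ae_type = set$ae_type, estimator = comparators,
                     tau = tau, estimate = unname(est), gold = gold,
                     row.names = NULL)
    rr <- lapply(df$estimate, ratio_vs_gold, gold = gold)
    df$ratio <- vapply(rr, `[[`, numeric(1), "ratio")
    df$log_ratio <- vapply(rr, `[[`, numeric(1), "log_ratio")
    if (!is.null(boot)) {
      m <- match(df$estimator, boot$estimator)
      df$se_log_ratio <- boot$se_log_ratio[m]
      df$ci_low <- boot$ci_low[m]
      df$ci_high <- boot$ci_high[m]
      df$n_degenerate <- boot$n_degenerate[m]
    } else {
      df$se_log_ratio <- NA_real_
      df$ci_low <- NA_real_
      df$ci_high <- NA_real_
      df$n_degenerate <- NA_integer_
    }
    df$pct_censoring <- cov$pct_censoring
    df$pct_ce <- cov$pct_ce
    df$tau_years <- cov$tau_years
    df$aje_probability <- cov$aje_probability
    df$excluded <- !vapply(rr, `[[`, logical(1), "defined") |
      !is.finite(df$se_log_ratio) | (!is.na(df$se_log_ratio) &
                                       df$se_log_ratio <= 0)
    df$reason <- ifelse(df$gold <= 0, "gold estimate zero",
                        ifelse(df$estimate <= 0, "comparator estimate zero",
                               ifelse(df$excluded, "no usable bootstrap SE",
                                      "")))
    rows[[i]] <- df
  }
  do.call(rbind, rows)
}

# Deterministic per-unit seed stream below 2^31.
derive_seeds <- function(seed, k) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}
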