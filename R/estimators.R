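# One-sample estimators of the cumulative AE probability at an evaluation
# time tau. All six estimators share the time-to-first-event data model:
# per patient one follow-up time and one of {censored, AE, death before AE,
# other CE}. The nonparametric Aalen-Johansen estimator of the AE
# cumulative incidence function is the reference ("gold standard") the
# others are compared against.

# Risk table at the distinct observed times: at-risk counts and per-state
# event counts. Ties between events and censorings at the same time follow
# the standard survival convention: a patient censored at t is still at
# risk for an event at t.
risk_table <- function(time, is_ae, is_ce) {
  tt <- sort(unique(time))
  idx <- match(time, tt)
  k <- length(tt)
  per_time <- tabulate(idx, nbins = k)
  d_ae <- tabulate(idx[is_ae], nbins = k)
  d_ce <- tabulate(idx[is_ce], nbins = k)
  at_risk <- length(time) - c(0, cumsum(per_time))[seq_len(k)]
  list(time = tt, at_risk = at_risk, d_ae = d_ae, d_ce = d_ce,
       d_all = d_ae + d_ce)
}

# Value of a right-continuous step function at tau: the value after the
# largest jump <= tau, or `init` before the first jump.
step_value <- function(times, values, tau, init) {
  i <- findInterval(tau, times)
  if (i == 0L) init else values[i]
}

set_ae_ce <- function(set, scheme = "all_ce") {
  set <- apply_ce_scheme(set, scheme)
  list(time = set$data$time,
       is_ae = set$data$outcome == "ae",
       is_ce = set$data$outcome %in% c("death_before_ae", "other_ce"))
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0)
    stop("tau must be a single strictly positive evaluation time",
         call. = FALSE)
  tau
}

#' Incidence proportion
#'
#' Number of patients with an observed AE on `[0, tau]` divided by the
#' number of patients. Accounts for competing events by construction but
#' ignores censoring, hence tends to underestimate the cumulative AE
#' probability when follow-up is incomplete.
#'
#' @param set An [analysis_set()].
#' @param tau Evaluation time in days.
#' @return Point estimate in `[0, 1]`.
#' @export
incidence_proportion <- function(set, tau) {
  stopifnot(inherits(set, "analysis_set"))
  check_tau(tau)
  sum(set$data$outcome == "ae" & set$data$time <= tau) / nrow(set$data)
}

#' Patient-time at risk restricted by tau
#'
#' @param set An [analysis_set()].
#' @param tau Evaluation time in days.
#' @return Total patient-days `sum(pmin(time_i, tau))`.
#' @export
patient_time <- function(set, tau) {
  stopifnot(inherits(set, "analysis_set"))
  check_tau(tau)
  sum(pmin(set$data$time, tau))
}

#' AE and competing-event incidence densities
#'
#' The AE incidence density (exposure-adjusted incidence rate) is the
#' number of patients with an observed AE on `[0, tau]` divided by the
#' patient-time at risk restricted by `tau`; it estimates a constant AE
#' hazard. `ce_incidence_density` is the analogue for competing events.
#'
#' @param set An [analysis_set()].
#' @param tau Evaluation time in days.
#' @param scheme Competing-event scheme, see [apply_ce_scheme()] (affects
#'   only the competing density).
#' @return Rate per patient-day.
#' @export
incidence_density <- function(set, tau) {
  pt <- patient_time(set, tau)
  if (pt <= 0) stop("total patient-time at risk is zero", call. = FALSE)
  sum(set$data$outcome == "ae" & set$data$time <= tau) / pt
}

#' @rdname incidence_density
#' @export
ce_incidence_density <- function(set, tau, scheme = "all_ce") {
  set <- apply_ce_scheme(set, scheme)
  pt <- patient_time(set, tau)
  if (pt <= 0) stop("total patient-time at risk is zero", call. = FALSE)
  n_ce <- sum(set$data$outcome %in% c("death_before_ae", "other_ce") &
                set$data$time <= tau)
  n_ce / pt
}

#' Probability transform of the incidence density, ignoring competing events
#'
#' Transforms the AE incidence density `ID` onto the probability scale as
#' `1 - exp(-ID * tau)`, i.e., the constant-hazard cumulative probability
#' with no allowance for competing events. Overestimates the cumulative AE
#' probability whenever competing hazards are present.
#'
#' @inheritParams incidence_proportion
#' @return Point estimate in `[0, 1]`.
#' @export
prob_transform_id_ignoring_ce <- function(set, tau) {
  1 - exp(-incidence_density(set, tau) * tau)
}

#' Probability transform of the incidence density, accounting for competing
#' events
#'
#' With AE density `a` and competing density `b`, returns
#' `a / (a + b) * (1 - exp(-tau * (a + b)))`, the constant-hazard
#' cumulative incidence of the AE in the presence of a competing constant
#' hazard. When `b = 0` this reduces exactly to the ignoring-CE transform;
#' when `a + b = 0` the estimate is 0 by convention.
#'
#' @inheritParams incidence_proportion
#' @param scheme Competing-event scheme for the competing density.
#' @return Point estimate in `[0, 1]`.
#' @export
prob_transform_id_accounting_ce <- function(set, tau, scheme = "all_ce") {
  a <- incidence_density(set, tau)
  b <- ce_incidence_density(set, tau, scheme)
  if (a + b == 0) return(0)
  a / (a + b) * (1 - exp(-tau * (a + b)))
}

#' One minus Kaplan-Meier for the AE outcome
#'
#' Product-limit estimator that codes only observed AEs as events and
#' censors everything else (competing events included) on `[0, tau]`.
#' Because competing events are censored rather than treated as terminal,
#' it overestimates the cumulative AE probability in their presence.
#'
#' @inheritParams incidence_proportion
#' @return Point estimate in `[0, 1]`.
#' @export
one_minus_kaplan_meier <- function(set, tau) {
  stopifnot(inherits(set, "analysis_set"))
  check_tau(tau)
  d <- set$data
  rt <- risk_table(d$time, is_ae = d$outcome == "ae",
                   is_ce = rep(FALSE, nrow(d)))
  keep <- rt$d_ae > 0
  if (!any(keep)) return(0)
  surv <- cumprod(1 - rt$d_ae[keep] / rt$at_risk[keep])
  1 - step_value(rt$time[keep], surv, tau, init = 1)
}

# Aalen-Johansen cumulative incidence curves for the AE and the competing
# event: increments S(t-) * d_type / Y at each event time, with S the
# all-event Kaplan-Meier survival.
aj_curves <- function(time, is_ae, is_ce) {
  rt <- risk_table(time, is_ae, is_ce)
  keep <- rt$d_all > 0
  tt <- rt$time[keep]
  y <- rt$at_risk[keep]
  d_all <- rt$d_all[keep]
  s <- cumprod(1 - d_all / y)
  s_minus <- c(1, s[-length(s)])
  list(time = tt,
       cif_ae = cumsum(s_minus * rt$d_ae[keep] / y),
       cif_ce = cumsum(s_minus * rt$d_ce[keep] / y),
       surv_all = s)
}

#' Aalen-Johansen estimator of the cumulative AE probability
#'
#' Nonparametric estimator of the AE cumulative incidence function under
#' competing events: it decomposes one minus the all-event (AE or CE)
#' Kaplan-Meier estimator into the cumulative AE probability plus the
#' cumulative CE probability. It equals one minus Kaplan-Meier when no
#' competing events occur and equals the incidence proportion when no
#' censoring occurs before `tau`, and handles both at once — the reference
#' estimator the others are compared against.
#'
#' @inheritParams incidence_proportion
#' @param scheme `"all_ce"` (default, the gold-standard definition) or
#'   `"death_only"` (only death before AE competing, other CEs censored).
#' @return Point estimate in `[0, 1]`.
#' @export
aalen_johansen <- function(set, tau, scheme = "all_ce") {
  stopifnot(inherits(set, "analysis_set"))
  check_tau(tau)
  x <- set_ae_ce(set, scheme)
  cur <- aj_curves(x$time, x$is_ae, x$is_ce)
  step_value(cur$time, cur$cif_ae, tau, init = 0)
}

#' Aalen-Johansen cumulative incidence of the competing event
#'
#' Same decomposition as [aalen_johansen()], accumulating the competing
#' event increments instead. At every `tau` the AE and CE cumulative
#' incidences add up to one minus the all-event Kaplan-Meier survival.
#'
#' @inheritParams aalen_johansen
#' @return Point estimate in `[0, 1]`.
#' @export
aje_ce_incidence <- function(set, tau, scheme = "all_ce") {
  stopifnot(inherits(set, "analysis_set"))
  check_tau(tau)
  x <- set_ae_ce(set, scheme)
  cur <- aj_curves(x$time, x$is_ae, x$is_ce)
  step_value(cur$time, cur$cif_ce, tau, init = 0)
}

#' Aalen-Johansen and all-event Kaplan-Meier step curves
#'
#' Returns the full right-continuous step curves supporting
#' [aalen_johansen()]: jump times, the AE and CE cumulative incidence
#' values after each jump, and the all-event Kaplan-Meier survival.
#'
#' @inheritParams aalen_johansen
#' @return Data frame with columns `time`, `cif_ae`, `cif_ce`, `surv_all`.
#' @export
aje_curve <- function(set, scheme = "all_ce") {
  stopifnot(inherits(set, "analysis_set"))
  x <- set_ae_ce(set, scheme)
  cur <- aj_curves(x$time, x$is_ae, x$is_ce)
  data.frame(time = cur$time, cif_ae = cur$cif_ae, cif_ce = cur$cif_ce,
             surv_all = cur$surv_all)
}

#' Evaluation time from a tau rule
#'
#' Estimators are compared at an evaluation time `tau`: either the maximum
#' observed follow-up time, or a quantile of the observed times. With
#' several arms the quantile is computed per arm and the minimum across
#' arms is used. Quantiles are nearest-rank (ceiling) empirical quantiles,
#' so the result is always an observed time.
#'
#' @param sets A single [analysis_set()] or a list of them (grouped by
#'   their `arm` label).
#' @param rule `"max"` for maximum follow-up, or a quantile in (0, 1];
#'   the study design uses 1.0, 0.9, 0.6 and 0.3.
#' @return Evaluation time in days.
#' @export
evaluation_time <- function(sets, rule = "max") {
  if (inherits(sets, "analysis_set")) sets <- list(sets)
  stopifnot(length(sets) >= 1L)
  arms <- vapply(sets, function(s) s$arm, character(1))
  times_by_arm <- lapply(split(sets, arms), function(group)
    unlist(lapply(group, function(s) s$data$time)))
  if (any(lengths(times_by_arm) == 0L))
    stop("every arm must contain at least one record", call. = FALSE)
  if (identical(rule, "max"))
    return(max(unlist(times_by_arm)))
  q <- as.numeric(rule)
  if (is.na(q) || q <= 0 || q > 1)
    stop("rule must be \"max\" or a quantile in (0, 1]", call. = FALSE)
  min(vapply(times_by_arm, function(x) {
    sort(x)[ceiling(q * length(x))]
  }, numeric(1)))
}

#' Names of the one-sample estimators
#'
#' The five comparator estimators plus the gold-standard Aalen-Johansen.
#' @return Character vector of estimator names accepted by
#'   [estimate_by_name()].
#' @export
estimator_names <- function() {
  c("ip", "ptid_ignore_ce", "one_minus_km", "ptid_acc_ce",
    "aje_death_only", "aje")
}

#' Evaluate a one-sample estimator by name
#'
#' @param set An [analysis_set()].
#' @param name One of [estimator_names()]: `"ip"` (incidence proportion),
#'   `"ptid_ignore_ce"` and `"ptid_acc_ce"` (probability transforms of the
#'   incidence density), `"one_minus_km"`, `"aje_death_only"`, `"aje"`.
#' @param tau Evaluation time in days.
#' @return Point estimate in `[0, 1]`.
#' @export
estimate_by_name <- function(set, name, tau) {
  switch(match.arg(name, estimator_names()),
         ip = incidence_proportion(set, tau),
         ptid_ignore_ce = prob_transform_id_ignoring_ce(set, tau),
         one_minus_km = one_minus_kaplan_meier(set, tau),
         ptid_acc_ce = prob_transform_id_accounting_ce(set, tau),
         aje_death_only = aalen_johansen(set, tau, scheme = "death_only"),
         aje = aalen_johansen(set, tau, scheme = "all_ce"))
}

#' All estimators on one analysis set
#'
#' Convenience wrapper evaluating all six estimators at `tau`, together
#' with the supporting counts and exposure summaries.
#'
#' @inheritParams incidence_proportion
#' @return Data frame with one row per estimator: `estimator`, `tau`,
#'   `estimate`, plus unit-level columns `n`, `patient_time`,
#'   `ae_incidence_density`, `ce_incidence_density`.
#' @export
estimate_all <- function(set, tau) {
  stopifnot(inherits(set, "analysis_set"))
  check_tau(tau)
  est <- vapply(estimator_names(), estimate_by_name, numeric(1),
                set = set, tau = tau)
  data.frame(estimator = estimator_names(),
             tau = tau,
             estimate = unname(est),
             n = nrow(set$data),
             patient_time = patient_time(set, tau),
             ae_incidence_density = incidence_density(set, tau),
             ce_incidence_density = ce_incidence_density(set, tau),
             row.names = NULL)
}
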