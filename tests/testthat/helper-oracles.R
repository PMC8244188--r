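# Brute-force survival oracles, deliberately independent of the package's
# aggregated risk-table implementation: they walk every distinct event
# time with explicitly enumerated risk sets.

# Product-limit estimator by direct enumeration; `event` marks the sole
# event type, everything else is censored at its time.
brute_km <- function(time, event, tau) {
  surv <- 1
  for (t in sort(unique(time[event & time <= tau]))) {
    at_risk <- sum(time >= t)
    d <- sum(event & time == t)
    surv <- surv * (1 - d / at_risk)
  }
  1 - surv
}

# Aalen-Johansen AE cumulative incidence by direct enumeration: all-event
# survival carried along, AE increments S(t-) * d_ae / Y.
brute_aje <- function(time, outcome, tau, cause = "ae") {
  is_ev <- outcome != "censored"
  is_cause <- if (cause == "ae") outcome == "ae" else
    outcome %in% c("death_before_ae", "other_ce")
  cif <- 0
  surv <- 1
  for (t in sort(unique(time[is_ev]))) {
    if (t > tau) break
    at_risk <- sum(time >= t)
    d_all <- sum(is_ev & time == t)
    d_cause <- sum(is_cause & time == t)
    cif <- cif + surv * d_cause / at_risk
    surv <- surv * (1 - d_all / at_risk)
  }
  cif
}

# Random small dataset with integer-valued times (to provoke ties) and
# all four outcome states.
random_small_set <- function(n, max_time = 6) {
  analysis_set(
    time = sample.int(max_time, n, replace = TRUE),
    outcome = sample(outcome_levels, n, replace = TRUE,
                     prob = c(0.3, 0.3, 0.2, 0.2)))
}
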