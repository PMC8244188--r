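# Competing-risks trial simulator with known truth. Patients carry latent
# cause-specific event times for the AE and the competing event (constant
# or Weibull hazards), plus an independent censoring time (administrative
# cut-off and optional exponential random censoring); the observed record
# is the earliest of the three with the matching outcome code. Competing
# events are split into death before AE and other competing events by a
# configurable fraction.

#' True cumulative AE incidence under constant hazards
#'
#' With a constant AE hazard `alpha` and competing hazard `beta`, the AE
#' cumulative incidence function at `tau` is
#' `alpha / (alpha + beta) * (1 - exp(-(alpha + beta) * tau))` — the
#' analytic oracle the simulator and the estimators are validated against.
#'
#' @param alpha AE hazard per day, `>= 0`.
#' @param beta Competing-event hazard per day, `>= 0`; not both zero.
#' @param tau Evaluation time in days, `> 0`.
#' @return Probability in `[0, 1]`.
#' @export
true_cumulative_incidence <- function(alpha, beta, tau) {
  stopifnot(alpha >= 0, beta >= 0, tau > 0)
  if (alpha + beta == 0)
    stop("alpha and beta cannot both be zero", call. = FALSE)
  alpha / (alpha + beta) * (1 - exp(-(alpha + beta) * tau))
}

draw_latent <- function(n, family, rate, shape, scale) {
  if (family == "constant") {
    if (rate == 0) rep(Inf, n) else stats::rexp(n, rate = rate)
  } else {
    if (scale <= 0) rep(Inf, n) else
      stats::rweibull(n, shape = shape, scale = scale)
  }
}

#' Simulate one (trial, arm, AE-type) analysis set
#'
#' Draws independent latent AE and competing-event times (constant-hazard
#' exponential by default, or Weibull cause-specific hazards), an
#' independent exponential random censoring time, and an administrative
#' cut-off; the record is the earliest of these with the corresponding
#' outcome. Competing events are split into death before AE vs. other
#' competing events with probability `death_frac` (default 0.25: in
#' time-to-first-AE data, deaths before AE are typically much rarer than
#' other reasons recording ends, such as treatment discontinuation).
#'
#' @param n Number of patients, `>= 1`.
#' @param ae_rate,ce_rate Constant hazards per day (ignored for the
#'   Weibull family).
#' @param family `"constant"` or `"weibull"`.
#' @param ae_shape,ae_scale,ce_shape,ce_scale Weibull cause-specific
#'   hazard parameters (shape 1 recovers constant hazard `1/scale`).
#' @param admin_time Administrative censoring time in days.
#' @param cens_rate Rate of additional independent exponential censoring
#'   (0 disables it).
#' @param death_frac Fraction of competing events that are deaths.
#' @param seed Optional integer seed for reproducibility.
#' @param trial_id,arm,ae_type Metadata labels.
#' @return An [analysis_set()].
#' @export
simulate_unit <- function(n, ae_rate = 2e-4, ce_rate = 1e-3,
                          family = c("constant", "weibull"),
                          ae_shape = 1, ae_scale = NULL,
                          ce_shape = 1, ce_scale = NULL,
                          admin_time = 900, cens_rate = 2e-4,
                          death_frac = 0.25, seed = NULL,
                          trial_id = "trial", arm = "E", ae_type = "AE") {
  family <- match.arg(family)
  stopifnot(n >= 1, admin_time > 0, cens_rate >= 0,
            death_frac >= 0, death_frac <= 1)
  if (family == "constant") {
    stopifnot(ae_rate >= 0, ce_rate >= 0)
  } else {
    if (is.null(ae_scale) || is.null(ce_scale))
      stop("weibull family needs ae_scale and ce_scale", call. = FALSE)
    stopifnot(ae_shape > 0, ce_shape > 0)
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  t_ae <- draw_latent(n, family, ae_rate, ae_shape, ae_scale)
  t_ce <- draw_latent(n, family, ce_rate, ce_shape, ce_scale)
  t_cens <- if (cens_rate > 0) stats::rexp(n, cens_rate) else rep(Inf, n)
  t_cens <- pmin(t_cens, admin_time)
  is_death <- stats::runif(n) < death_frac
  time <- pmin(t_ae, t_ce, t_cens)
  outcome <- ifelse(t_ae <= time & t_ae <= t_ce, "ae",
                    ifelse(t_ce <= time,
                           ifelse(is_death, "death_before_ae", "other_ce"),
                           "censored"))
  # continuous latent times make exact ties a probability-zero event, but
  # guard the degenerate all-zero-hazard case anyway
  time <- pmax(time, .Machine$double.eps)
  analysis_set(time, outcome, trial_id = trial_id, arm = arm,
               ae_type = ae_type)
}

#' Simulate a portfolio of trials with between-trial heterogeneity
#'
#' Emulates a meta-analytic portfolio: `n_trials` trials of varying size,
#' each contributing several AE types. Per-trial and per-AE-type
#' log-hazard perturbations are drawn as independent normals with the
#' stated heterogeneity standard deviations, so every unit has its own
#' known true hazards and true cumulative incidence. Defaults emulate the
#' study conditions of a large safety portfolio: trial sizes log-normal
#' between roughly 200 and 7000 patients (median near 450),
#' administrative follow-up around 900 days, and hazards giving on the
#' order of half the patients a competing event and a third censored at
#' maximum follow-up.
#'
#' @param n_trials Number of trials.
#' @param ae_types_per_trial AE types contributed by each trial.
#' @param n_range Admissible trial sizes (inclusive bounds).
#' @param median_n Median target for the log-normal trial-size draw.
#' @param ae_rate,ce_rate Baseline constant hazards per day.
#' @param admin_time Administrative censoring time in days.
#' @param cens_rate Random censoring rate per day.
#' @param death_frac Fraction of competing events that are deaths.
#' @param het_sd SD of per-trial log-hazard perturbations (applied to
#'   both hazards).
#' @param ae_type_sd SD of per-AE-type log-AE-hazard perturbations
#'   (AE types within a trial differ widely in frequency).
#' @param seed Integer master seed; trial and unit seeds derive from it.
#' @return List with `sets` (list of [analysis_set()]) and `truth` (data
#'   frame of per-unit hazards and true cumulative incidence at
#'   `admin_time`).
#' @export
simulate_portfolio <- function(n_trials = 17, ae_types_per_trial = 6,
                               n_range = c(200, 7171), median_n = 443,
                               ae_rate = 2e-4, ce_rate = 1e-3,
                               admin_time = 900, cens_rate = 2e-4,
                               death_frac = 0.25, het_sd = 0.3,
                               ae_type_sd = 0.8, seed = 1L) {
  stopifnot(n_trials >= 1, ae_types_per_trial >= 1, het_sd >= 0,
            ae_type_sd >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_pat <- round(stats::rlnorm(n_trials, meanlog = log(median_n),
                               sdlog = 0.9))
  n_pat <- pmin(pmax(n_pat, n_range[1]), n_range[2])
  trial_shift <- stats::rnorm(n_trials, 0, het_sd)
  unit_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                  n_trials * ae_types_per_trial),
                       nrow = n_trials)
  sets <- list()
  truth <- list()
  for (i in seq_len(n_trials)) {
    ae_shift <- stats::rnorm(ae_types_per_trial, 0, ae_type_sd)
    for (j in seq_len(ae_types_per_trial)) {
      alpha <- ae_rate * exp(trial_shift[i] + ae_shift[j])
      beta <- ce_rate * exp(trial_shift[i])
      id <- sprintf("trial%02d", i)
      ae_id <- sprintf("AE%02d", j)
      sets[[length(sets) + 1L]] <-
        simulate_unit(n_pat[i], ae_rate = alpha, ce_rate = beta,
                      admin_time = admin_time, cens_rate = cens_rate,
                      death_frac = death_frac, seed = unit_seeds[i, j],
                      trial_id = id, ae_type = ae_id)
      truth[[length(truth) + 1L]] <-
        data.frame(trial_id = id, ae_type = ae_id, n = n_pat[i],
                   ae_hazard = alpha, ce_hazard = beta,
                   true_cif = true_cumulative_incidence(alpha, beta,
                                                        admin_time),
                   row.names = NULL)
    }
  }
  list(sets = sets, truth = do.call(rbind, truth))
}

#' Reconstruct an analysis set from aggregate event counts
#'
#' Builds a deterministic analysis set matching given counts of AEs,
#' deaths before AE, other competing events and censored observations,
#' with event times spread evenly over `(0, tau]` and censoring times at
#' or before `tau`. Useful for reproducing worked examples that report
#' only aggregate counts; the times are synthetic, so only count-based
#' quantities (incidence proportion, event percentages) are meaningful.
#'
#' @param n_ae,n_death,n_other_ce,n_censored Non-negative event counts.
#' @param tau Maximum follow-up time in days (default 900).
#' @param trial_id,arm,ae_type Metadata labels.
#' @return An [analysis_set()] with `n_ae + n_death + n_other_ce +
#'   n_censored` records.
#' @export
set_from_counts <- function(n_ae, n_death, n_other_ce, n_censored,
                            tau = 900, trial_id = "trial", arm = "E",
                            ae_type = "AE") {
  counts <- c(n_ae, n_death, n_other_ce, n_censored)
  stopifnot(all(counts >= 0), sum(counts) >= 1, tau > 0)
  spread <- function(k, lo, hi) if (k == 0) numeric(0) else
    seq(lo, hi, length.out = k + 1L)[-1L]
  time <- c(spread(n_ae, 0, 0.4 * tau),
            spread(n_death, 0, 0.6 * tau),
            spread(n_other_ce, 0, 0.8 * tau),
            spread(n_censored, 0.2 * tau, tau))
  outcome <- rep(c("ae", "death_before_ae", "other_ce", "censored"),
                 counts)
  analysis_set(time, outcome, trial_id = trial_id, arm = arm,
               ae_type = ae_type)
}
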