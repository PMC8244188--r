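test_that("incidence proportion and density match hand values", {
  expect_equal(incidence_proportion(set_from_counts(3, 17, 180, 74), 900),
               3 / 274)
  expect_equal(incidence_proportion(set_from_counts(44, 137, 95, 476), 900),
               44 / 752)
  expect_equal(incidence_proportion(set_from_counts(0, 1, 1, 8), 900), 0)

  one <- analysis_set(10, "ae")
  expect_equal(incidence_density(one, 10), 0.1)
  expect_equal(incidence_density(set_from_counts(0, 0, 0, 5), 900), 0)
  expect_equal(patient_time(analysis_set(c(5, 20), c("ae", "censored")), 10),
               15)
})

test_that("probability transforms of the incidence density are exact in closed form", {
  one <- analysis_set(10, "ae")
  expect_equal(prob_transform_id_ignoring_ce(one, 10), 1 - exp(-1))
  expect_equal(prob_transform_id_ignoring_ce(set_from_counts(0, 0, 0, 5), 900),
               0)
  # zero competing density: accounting-for-CE transform reduces exactly to
  # the ignoring-CE transform
  set.seed(11)
  s <- analysis_set(rexp(40, 0.1) + 0.1,
                    sample(c("ae", "censored"), 40, replace = TRUE))
  for (tau in c(2, 5, 20)) {
    expect_equal(prob_transform_id_accounting_ce(s, tau),
                 prob_transform_id_ignoring_ce(s, tau))
  }
  # neither AEs nor CEs: estimate 0 by convention
  expect_equal(prob_transform_id_accounting_ce(set_from_counts(0, 0, 0, 4),
                                               900), 0)
})

test_that("one minus Kaplan-Meier matches the hand product-limit", {
  s <- analysis_set(c(1, 2, 3), c("other_ce", "ae", "censored"))
  expect_equal(one_minus_kaplan_meier(s, 3), 0.5)
  expect_equal(one_minus_kaplan_meier(set_from_counts(0, 2, 3, 5), 900), 0)
  # with complete follow-up (no censoring, no CE) KM reduces to IP
  cmp <- analysis_set(c(1, 2, 4, 9), rep("ae", 4))
  expect_equal(one_minus_kaplan_meier(cmp, 9), incidence_proportion(cmp, 9))
})

test_that("Aalen-Johansen matches hand values and decomposition identities", {
  s <- analysis_set(c(1, 2, 3), c("other_ce", "ae", "censored"))
  expect_equal(aalen_johansen(s, 3), 1 / 3)
  expect_equal(aje_ce_incidence(s, 3), 1 / 3)

  set.seed(23)
  for (i in 1:50) {
    s <- random_small_set(sample(2:30, 1))
    tau <- max(s$data$time)
    # no CEs: AJE equals one minus Kaplan-Meier at every tau
    no_ce <- s
    no_ce$data$outcome[no_ce$data$outcome %in%
                         c("death_before_ae", "other_ce")] <- "censored"
    for (tt in unique(no_ce$data$time))
      expect_equal(aalen_johansen(no_ce, tt),
                   one_minus_kaplan_meier(no_ce, tt))
    # no censoring: AJE equals the incidence proportion
    no_cens <- s
    no_cens$data$outcome[no_cens$data$outcome == "censored"] <- "other_ce"
    expect_equal(aalen_johansen(no_cens, tau),
                 incidence_proportion(no_cens, tau))
    # decomposition: AE-CIF + CE-CIF = 1 - all-event KM
    comp <- s
    comp$data$outcome[comp$data$outcome != "censored"] <- "ae"
    expect_equal(aalen_johansen(s, tau) + aje_ce_incidence(s, tau),
                 one_minus_kaplan_meier(comp, tau))
  }
})

test_that("KM and AJE agree with brute-force risk-set enumeration and survival/cmprsk", {
  set.seed(101)
  for (i in 1:200) {
    s <- random_small_set(sample(2:8, 1))
    tau <- sample(1:7, 1)
    d <- s$data
    expect_equal(one_minus_kaplan_meier(s, tau),
                 brute_km(d$time, d$outcome == "ae", tau),
                 tolerance = 1e-12)
    expect_equal(aalen_johansen(s, tau), brute_aje(d$time, d$outcome, tau),
                 tolerance = 1e-12)
    expect_equal(aje_ce_incidence(s, tau),
                 brute_aje(d$time, d$outcome, tau, cause = "ce"),
                 tolerance = 1e-12)
  }
})

test_that("AJE matches the cmprsk and survival reference implementations", {
  skip_if_not_installed("cmprsk")
  skip_if_not_installed("survival")
  set.seed(55)
  for (i in 1:20) {
    s <- random_small_set(sample(4:12, 1))
    d <- s$data
    tau <- max(d$time)
    status <- ifelse(d$outcome == "censored", 0,
                     ifelse(d$outcome == "ae", 1, 2))
    if (!any(status == 1)) next
    ci <- cmprsk::cuminc(d$time, status, cencode = 0)
    if (!is.null(ci$`1 1`)) {
      ref <- ci$`1 1`
      expect_equal(aalen_johansen(s, tau), ref$est[max(which(ref$time <= tau))],
                   tolerance = 1e-10)
    }
    sf <- survival::survfit(
      survival::Surv(d$time, factor(status, levels = 0:2)) ~ 1)
    p_ae <- summary(sf, times = tau,
                    extend = TRUE)$pstate[, match("1", sf$states)]
    expect_equal(aalen_johansen(s, tau), unname(p_ae), tolerance = 1e-10)
  }
})

test_that("estimator ordering reflects how each handles censoring and CEs", {
  set.seed(77)
  for (i in 1:100) {
    s <- random_small_set(sample(3:40, 1))
    tau <- sample(1:6, 1)
    km <- one_minus_kaplan_meier(s, tau)
    aje <- aalen_johansen(s, tau)
    ip <- incidence_proportion(s, tau)
    expect_gte(km, aje - 1e-12)
    expect_gte(aje, ip - 1e-12)
    # death-only AJE censors other CEs, so it dominates the all-CE AJE
    expect_gte(aalen_johansen(s, tau, "death_only"), aje - 1e-12)
    d <- s$data
    if (!any(d$outcome == "other_ce" & d$time <= tau))
      expect_equal(aalen_johansen(s, tau, "death_only"), aje)
  }
})

test_that("evaluation_time implements max and nearest-rank quantile rules", {
  one <- analysis_set(c(1, 2, 3), c("ae", "censored", "censored"))
  expect_equal(evaluation_time(one, "max"), 3)
  expect_equal(evaluation_time(one, 1.0), 3)

  a <- analysis_set(c(50, 100), c("censored", "censored"), arm = "E")
  b <- analysis_set(c(40, 80), c("censored", "censored"), arm = "C")
  expect_equal(evaluation_time(list(a, b), 1.0), 80)
  expect_equal(evaluation_time(list(a, b), "max"), 100)

  dec <- analysis_set(seq(10, 100, by = 10), rep("censored", 10))
  expect_equal(evaluation_time(dec, 0.9), 90)
  expect_equal(evaluation_time(dec, 0.3), 30)
  expect_error(evaluation_time(dec, 1.5), "quantile")
})

test_that("large-sample estimates converge to the constant-hazard truth", {
  alpha <- 0.001; beta <- 0.002; tau <- 900
  u <- simulate_unit(1e5, ae_rate = alpha, ce_rate = beta,
                     admin_time = tau, cens_rate = 0, seed = 900)
  truth <- true_cumulative_incidence(alpha, beta, tau)
  expect_equal(aalen_johansen(u, tau), truth, tolerance = 0.02)
  expect_equal(prob_transform_id_accounting_ce(u, tau), truth,
               tolerance = 0.01)
  expect_equal(incidence_density(u, tau), alpha, tolerance = 0.05)
  # ignoring the competing hazard overestimates: limit 1 - exp(-alpha*tau
  # *c) with c > 1 from shortened at-risk time, above the true CIF
  expect_gt(prob_transform_id_ignoring_ce(u, tau), truth + 0.05)
})
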