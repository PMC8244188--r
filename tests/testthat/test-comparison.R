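test_that("ratio_vs_gold divides point estimates and flags zeros", {
  r <- ratio_vs_gold(0.059, 0.109)
  expect_equal(round(r$ratio, 3), 0.541)
  expect_equal(r$log_ratio, log(0.059 / 0.109))
  expect_true(r$defined)
  expect_equal(ratio_vs_gold(0.1, 0.1)$ratio, 1)
  expect_false(ratio_vs_gold(0.1, 0)$defined)
  expect_false(ratio_vs_gold(0, 0.1)$defined)
})

test_that("bootstrap SE is zero for degenerate identical records and deterministic", {
  ident <- analysis_set(rep(5, 12), rep("ae", 12))
  b <- bootstrap_log_ratio_se(ident, "ip", B = 20, seed = 1)
  expect_equal(b$se, 0)

  u <- simulate_unit(120, seed = 4)
  b1 <- bootstrap_unit_ratios(u, B = 100, seed = 99)
  b2 <- bootstrap_unit_ratios(u, B = 100, seed = 99)
  expect_identical(b1, b2)
  b3 <- bootstrap_unit_ratios(u, B = 100, seed = 100)
  expect_false(identical(b1$se_log_ratio, b3$se_log_ratio))
})

test_that("bootstrap does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  invisible(bootstrap_unit_ratios(simulate_unit(50, seed = 2), B = 10,
                                  seed = 7))
  expect_identical(runif(1), before)
})

test_that("bootstrap SE approximates the sampling SD of the log-ratio", {
  # Monte-Carlo oracle: the empirical SD of log(1-KM / AJE) over many
  # independently simulated datasets, versus one dataset's bootstrap SE.
  alpha <- 1e-3; beta <- 2e-3; n <- 300
  sim_lr <- function(seed) {
    u <- simulate_unit(n, ae_rate = alpha, ce_rate = beta,
                       admin_time = 900, cens_rate = 5e-4, seed = seed)
    tau <- evaluation_time(u, "max")
    log(one_minus_kaplan_meier(u, tau) / aalen_johansen(u, tau))
  }
  emp <- vapply(1:1000, sim_lr, numeric(1))
  u <- simulate_unit(n, ae_rate = alpha, ce_rate = beta, admin_time = 900,
                     cens_rate = 5e-4, seed = 20)
  b <- bootstrap_log_ratio_se(u, "one_minus_km", "max", B = 1000, seed = 21)
  expect_equal(b$se, sd(emp), tolerance = 0.15)
})

test_that("composite endpoint isolates the censoring effect", {
  s <- analysis_set(c(1, 2, 3), c("ae", "censored", "other_ce"))
  cmp <- composite_endpoint_analysis(s, 3)
  expect_equal(cmp$ip_composite, 2 / 3)
  expect_equal(cmp$one_minus_km_composite, 1)
  expect_equal(cmp$ratio, 2 / 3)

  # without censoring the composite KM equals the composite IP
  full <- analysis_set(c(1, 2, 4), c("ae", "death_before_ae", "other_ce"))
  expect_equal(composite_endpoint_analysis(full, 4)$ratio, 1)

  set.seed(33)
  for (i in 1:50) {
    s <- random_small_set(sample(3:30, 1))
    r <- composite_endpoint_analysis(s, sample(1:6, 1))$ratio
    if (!is.na(r)) expect_lte(r, 1 + 1e-12)
  }
})

test_that("summarize_unit reports the meta-regression covariates", {
  ex1 <- set_from_counts(3, 17, 180, 74)
  cov <- summarize_unit(ex1, 900)
  expect_equal(round(cov$pct_censoring, 1), 27.0)
  expect_equal(cov$pct_ce, 100 * (17 + 180) / 274)
  expect_equal(cov$tau_years, 900 / 365.25)

  ex2 <- set_from_counts(44, 137, 95, 476)
  expect_equal(round(summarize_unit(ex2, 900)$pct_censoring, 1), 63.3)

  allc <- set_from_counts(0, 0, 0, 10)
  cov3 <- summarize_unit(allc, 900)
  expect_equal(cov3$pct_censoring, 100)
  expect_equal(cov3$aje_probability, 0)
})

test_that("compare_units flags undefined ratios and mirrors the bias direction", {
  pf <- simulate_portfolio(n_trials = 5, ae_types_per_trial = 3,
                           ce_rate = 2e-3, seed = 61)
  ratios <- compare_units(pf$sets, B = 60, seed = 62)
  expect_equal(nrow(ratios), 15 * 5)
  ok <- ratios[!ratios$excluded, ]
  km <- ok[ok$estimator == "one_minus_km", ]
  dth <- ok[ok$estimator == "aje_death_only", ]
  # overestimation direction when CEs are present before tau
  expect_true(all(km$ratio >= 1 - 1e-12))
  expect_true(all(dth$ratio >= 1 - 1e-12))
  expect_true(all(ok$ci_low <= ok$ci_high))
  expect_true(all(ok$se_log_ratio > 0))
  # zero-AE unit: gold is zero, every row of that unit flagged
  none <- set_from_counts(0, 5, 10, 20, trial_id = "z")
  r0 <- compare_units(list(none), B = 10, seed = 1)
  expect_true(all(r0$excluded))
  expect_true(all(r0$reason == "gold estimate zero"))
})
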