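test_that("random-effects pooling handles degenerate and equal-weight cases", {
  f0 <- fit_random_effects(rep(0, 6), rep(0.1, 6))
  expect_equal(f0$average_ratio, 1)
  expect_equal(f0$tau2, 0)

  # fixed-effect model with equal SEs is the arithmetic mean
  y <- c(log(1.1), log(1.4))
  ffe <- fit_random_effects(y, c(0.2, 0.2), method = "FE")
  expect_equal(ffe$mu, mean(y), tolerance = 1e-10)
  expect_equal(ffe$tau2, 0)

  # fixed-effect model equals the closed-form inverse-variance estimate
  set.seed(13)
  y <- rnorm(10); se <- runif(10, 0.05, 0.3)
  w <- 1 / se^2
  expect_equal(fit_random_effects(y, se, method = "FE")$mu,
               sum(w * y) / sum(w), tolerance = 1e-10)

  expect_error(fit_random_effects(1, 0.1), "at least 2")
  expect_error(fit_random_effects(c(0, 1), c(0.1, 0)), "positive")
})

test_that("REML pooling recovers a planted average ratio", {
  # 150 units, true mean log-ratio log(1.2), heterogeneity SD 0.05
  set.seed(202)
  reps <- vapply(1:200, function(r) {
    se <- runif(150, 0.03, 0.10)
    y <- log(1.2) + rnorm(150, 0, 0.05) + rnorm(150, 0, se)
    fit_random_effects(y, se)$average_ratio
  }, numeric(1))
  expect_equal(mean(reps), 1.2, tolerance = 0.01)
  expect_lt(sd(reps), 0.05)
})

test_that("meta-regression recovers a planted censoring slope", {
  set.seed(303)
  n <- 120
  cens <- runif(n, 5, 70)
  se <- runif(n, 0.03, 0.08)
  b_true <- 0.02  # per percentage point of censoring
  y <- log(1.2) + b_true * (cens - mean(cens)) + rnorm(n, 0, se)
  d <- data.frame(log_ratio = y, se_log_ratio = se, pct_censoring = cens)
  fit <- meta_regression(d, covariates = "pct_censoring",
                         multivariable = TRUE)
  expect_equal(fit$coefficients$slope_log, b_true, tolerance = 0.1)
  # reported multiplicative change is per 10 percentage points
  expect_equal(fit$coefficients$increment, 10)
  expect_equal(fit$coefficients$ratio_change,
               exp(fit$coefficients$slope_log * 10))
  expect_equal(fit$average_ratio, 1.2, tolerance = 0.03)
})

test_that("centering leaves slopes unchanged and only shifts the intercept", {
  set.seed(404)
  n <- 60
  x <- runif(n, 0, 50)
  se <- runif(n, 0.04, 0.1)
  y <- 0.1 + 0.01 * x + rnorm(n, 0, se)
  d1 <- data.frame(y = y, se = se, pct_censoring = x)
  d2 <- data.frame(y = y, se = se, pct_censoring = x + 25)  # shifted
  f1 <- meta_regression(d1, "pct_censoring", multivariable = TRUE)
  f2 <- meta_regression(d2, "pct_censoring", multivariable = TRUE)
  expect_equal(f1$coefficients$slope_log, f2$coefficients$slope_log,
               tolerance = 1e-8)
  expect_equal(f1$average_ratio, f2$average_ratio, tolerance = 1e-8)
})

test_that("constant covariates drop out and zero covariates reduce to plain pooling", {
  set.seed(505)
  y <- rnorm(20, log(1.1), 0.1); se <- runif(20, 0.05, 0.1)
  d <- data.frame(y = y, se = se, pct_censoring = rep(30, 20))
  fit <- meta_regression(d, "pct_censoring", multivariable = TRUE)
  base <- fit_random_effects(y, se)
  expect_equal(fit$coefficients$slope_log, 0)
  expect_equal(fit$average_ratio, base$average_ratio, tolerance = 1e-10)
  expect_equal(fit$tau2, base$tau2, tolerance = 1e-8)
})

test_that("univariable mode fits one model per covariate", {
  set.seed(606)
  n <- 50
  d <- data.frame(log_ratio = rnorm(n, 0.1, 0.1),
                  se_log_ratio = runif(n, 0.05, 0.1),
                  pct_censoring = runif(n, 0, 60),
                  aje_probability = runif(n, 0, 0.5),
                  tau_years = runif(n, 0.5, 4))
  fits <- meta_regression(d, multivariable = FALSE)
  expect_named(fits, c("pct_censoring", "aje_probability", "tau_years"))
  for (f in fits) expect_equal(nrow(f$coefficients), 1L)
  # the default multivariable covariate list omits pct_ce (collinear with
  # censoring and the AE probability)
  expect_false("pct_ce" %in% eval(formals(meta_regression)$covariates))
})

test_that("meta_by_estimator pools per estimator and drops excluded rows", {
  pf <- simulate_portfolio(n_trials = 5, ae_types_per_trial = 3, seed = 71)
  ratios <- compare_units(pf$sets, B = 50, seed = 72)
  meta <- meta_by_estimator(ratios)
  expect_setequal(meta$estimator, setdiff(estimator_names(), "aje"))
  expect_true(all(meta$average_ratio > 0))
  expect_true(all(meta$ci_low <= meta$average_ratio &
                    meta$average_ratio <= meta$ci_high))
  expect_true(all(meta$tau2 >= 0))
})
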