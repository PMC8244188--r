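# Random-effects meta-analysis and meta-regression of log-ratios across
# (trial, AE-type) units. The model is the normal-normal hierarchical
# model: y_i ~ N(mu, se_i^2 + tau2), fitted with metafor; exp(mu) is the
# average ratio of a comparator estimator to the gold standard.

#' Random-effects meta-analysis of log-ratios
#'
#' Pools unit-level log-ratios under the normal-normal hierarchical model
#' `y_i ~ N(mu, se_i^2 + tau2)`. The between-unit heterogeneity variance
#' `tau2` is estimated by REML by default (DerSimonian-Laird available for
#' sensitivity, and `"FE"` constrains `tau2 = 0`, giving the closed-form
#' inverse-variance fixed-effect estimate). Confidence intervals are Wald
#' intervals on the log scale, optionally with the Knapp-Hartung
#' adjustment.
#'
#' @param y Numeric vector of log-ratios (finite).
#' @param se Positive within-unit standard errors of the log-ratios
#'   (bootstrap SEs).
#' @param method Heterogeneity estimator: `"REML"` (default), `"DL"`, or
#'   `"FE"` for the fixed-effect model.
#' @param knha Use the Knapp-Hartung adjustment for the CI.
#' @return List with `mu` (pooled mean log-ratio), `average_ratio`
#'   (`exp(mu)`), `tau2`, `ci_low`/`ci_high` on the ratio scale, `k`
#'   (number of units), and the underlying metafor `fit`.
#' @export
fit_random_effects <- function(y, se, method = c("REML", "DL", "FE"),
                               knha = FALSE) {
  method <- match.arg(method)
  if (length(y) < 2L)
    stop("meta-analysis needs at least 2 units", call. = FALSE)
  if (length(se) != length(y) || anyNA(se) || any(se <= 0))
    stop("standard errors must be positive and paired with y",
         call. = FALSE)
  if (anyNA(y) || any(!is.finite(y)))
    stop("log-ratios must be finite", call. = FALSE)
  fit <- metafor::rma(yi = y, sei = se, method = method,
                      test = if (knha) "knha" else "z")
  list(mu = as.numeric(fit$beta),
       average_ratio = exp(as.numeric(fit$beta)),
       tau2 = fit$tau2,
       ci_low = exp(fit$ci.lb),
       ci_high = exp(fit$ci.ub),
       k = fit$k,
       fit = fit)
}

# Reporting increments for the meta-regression slopes: multiplicative
# change in the average ratio per 10 percentage points of censoring or
# competing events, per 0.1 of gold-standard AE probability, per 1 year
# of evaluation time.
covariate_increments <- c(pct_censoring = 10, pct_ce = 10,
                          aje_probability = 0.1, tau_years = 1)

#' Mixed-effects meta-regression on centered covariates
#'
#' Regresses unit-level log-ratios on covariates centered at their means
#' over the analysed units, with residual between-unit heterogeneity.
#' Centering makes the exponentiated intercept interpretable as the
#' average ratio for a unit with mean covariate values; slopes are
#' reported as the multiplicative change in the average ratio per a
#' conventional increment (10 percentage points of censoring or competing
#' events, 0.1 of AE probability, 1 year of evaluation time).
#'
#' A covariate that is constant across units carries no information: it is
#' dropped with slope 0 rather than producing a rank-deficient design.
#'
#' @param data Data frame with columns `log_ratio` (or `y`),
#'   `se_log_ratio` (or `se`) and the covariate columns.
#' @param covariates Covariate column names; defaults to the three
#'   covariates of the multivariable model (`pct_ce` is omitted there by
#'   default because of its strong dependence on censoring and the AE
#'   probability, but can be requested explicitly).
#' @param multivariable Fit one joint model (`TRUE`) or one univariable
#'   model per covariate (`FALSE`, default).
#' @inheritParams fit_random_effects
#' @return For a multivariable fit, a list with `average_ratio`,
#'   `ci_low`/`ci_high`, `tau2`, `k` and a `coefficients` data frame
#'   (covariate, increment, log-scale slope, multiplicative
#'   `ratio_change` per increment with CI). For univariable fits, a named
#'   list of such results, one per covariate.
#' @export
meta_regression <- function(data,
                            covariates = c("pct_censoring",
                                           "aje_probability", "tau_years"),
                            multivariable = FALSE,
                            method = c("REML", "DL", "FE"),
                            knha = FALSE) {
  method <- match.arg(method)
  y <- if ("log_ratio" %in% names(data)) data$log_ratio else data$y
  se <- if ("se_log_ratio" %in% names(data)) data$se_log_ratio else data$se
  stopifnot(!is.null(y), !is.null(se),
            all(covariates %in% names(data)))
  if (!multivariable) {
    out <- lapply(covariates, function(cv)
      meta_regression(data, covariates = cv, multivariable = TRUE,
                      method = method, knha = knha))
    names(out) <- covariates
    return(out)
  }
  if (length(y) < length(covariates) + 2L)
    stop("too few units for the requested number of coefficients",
         call. = FALSE)
  x <- as.matrix(data[covariates])
  ctr <- scale(x, center = TRUE, scale = FALSE)
  informative <- apply(ctr, 2, function(v) stats::sd(v) > 0)
  dropped <- covariates[!informative]
  kept <- covariates[informative]
  if (length(kept) == 0L) {
    base <- fit_random_effects(y, se, method = method, knha = knha)
    coefs <- zero_coef_rows(covariates)
    return(c(base[c("mu", "average_ratio", "tau2", "ci_low", "ci_high",
                    "k")],
             list(coefficients = coefs, fit = base$fit)))
  }
  mods <- ctr[, informative, drop = FALSE]
  fit <- metafor::rma(yi = y, sei = se, mods = mods, method = method,
                      test = if (knha) "knha" else "z")
  b <- as.numeric(fit$beta)
  names(b) <- rownames(fit$beta)
  inc <- covariate_increments[kept]
  inc[is.na(inc)] <- 1
  coefs <- data.frame(
    covariate = kept,
    increment = unname(inc),
    slope_log = unname(b[kept]),
    ratio_change = exp(unname(b[kept]) * unname(inc)),
    ci_low = exp(fit$ci.lb[match(kept, names(b))] * unname(inc)),
    ci_high = exp(fit$ci.ub[match(kept, names(b))] * unname(inc)),
    row.names = NULL)
  if (length(dropped) > 0L)
    coefs <- rbind(coefs, zero_coef_rows(dropped))
  coefs <- coefs[match(covariates, coefs$covariate), , drop = FALSE]
  rownames(coefs) <- NULL
  list(mu = b[["intrcpt"]],
       average_ratio = exp(b[["intrcpt"]]),
       tau2 = fit$tau2,
       ci_low = exp(fit$ci.lb[match("intrcpt", names(b))]),
       ci_high = exp(fit$ci.ub[match("intrcpt", names(b))]),
       k = fit$k,
       coefficients = coefs,
       fit = fit)
}

zero_coef_rows <- function(covariates) {
  inc <- covariate_increments[covariates]
  inc[is.na(inc)] <- 1
  data.frame(covariate = covariates, increment = unname(inc),
             slope_log = 0, ratio_change = 1,
             ci_low = NA_real_, ci_high = NA_real_, row.names = NULL)
}

#' Meta-analyse comparison output per estimator
#'
#' Groups the output of [compare_units()] by comparator estimator,
#' excludes rows flagged undefined (zero estimates or unusable bootstrap
#' SEs), and pools the remaining log-ratios with [fit_random_effects()].
#'
#' @param ratios Data frame from [compare_units()].
#' @inheritParams fit_random_effects
#' @return Data frame with one row per estimator: `average_ratio`,
#'   `ci_low`, `ci_high`, `tau2`, `k`, `n_excluded`.
#' @export
meta_by_estimator <- function(ratios, method = "REML", knha = FALSE) {
  res <- lapply(split(ratios, ratios$estimator), function(d) {
    ok <- !d$excluded
    fit <- fit_random_effects(d$log_ratio[ok], d$se_log_ratio[ok],
                              method = method, knha = knha)
    data.frame(estimator = d$estimator[1],
               average_ratio = fit$average_ratio,
               ci_low = fit$ci_low, ci_high = fit$ci_high,
               tau2 = fit$tau2, k = fit$k, n_excluded = sum(!ok),
               row.names = NULL)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
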