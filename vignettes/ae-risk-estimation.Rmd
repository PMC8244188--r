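---
title: "Estimating adverse event risk under competing events and censoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating adverse event risk under competing events and censoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerisk)
```

## The problem

Safety analyses in clinical trials routinely report the probability that
a patient experiences at least one adverse event (AE) of a given type.
Follow-up times vary between patients, observation can end without any
event (censoring), and other events — death before the AE, or disease- or
safety-related end of AE recording such as treatment discontinuation —
can preclude the AE from ever being observed (competing events, CEs).
The common summary statistics each mishandle one of these features:

* the **incidence proportion** (IP), patients with an observed AE divided
  by group size, handles CEs correctly but pretends censored patients
  were followed forever, so it underestimates;
* the **incidence density** (exposure-adjusted incidence rate) divides by
  patient-time at risk and handles censoring, but assumes a constant
  hazard, and its usual probability transform `1 - exp(-ID * tau)`
  ignores CEs entirely, so it overestimates — often severely;
* **one minus Kaplan-Meier** with AE as the only event type censors CEs,
  which implicitly assumes the AE would still eventually occur for
  patients who died first; it too overestimates;
* the **Aalen-Johansen estimator** (AJE) of the AE cumulative incidence
  function is the nonparametric estimator that accommodates censoring,
  non-constant hazards and CEs at once. It is the reference ("gold
  standard") every other estimator is compared against here.

This package implements the six estimators, the comparison machinery
(ratios to the gold standard on the log scale with bootstrap standard
errors, SmPC frequency-category cross-tabulations), a random-effects
meta-analysis/meta-regression layer that pools log-ratios across many
(trial, AE-type) units, and a competing-risks simulator with known truth
that stands in for a proprietary trial portfolio.

## Data model

One record per patient per AE type: a strictly positive follow-up time
in days and exactly one first-event outcome among *censored*, *AE*,
*death before AE* and *other CE* (file codes 0/1/2/3). Records with
non-positive or missing times are rejected at ingest rather than
dropped, so denominators stay honest. Two CE schemes are supported: the
default **all-CE** scheme treats death and other CEs as competing; the
**death-only** sensitivity scheme recodes other CEs to censored.

## Estimators and conventions

All estimators are evaluated at a time `tau`: either the maximum
observed follow-up time or a nearest-rank (ceiling) empirical quantile
of the observed times (1.0, 0.9, 0.6, 0.3 in the study design), taking
the minimum across arms when several arms are present. The nearest-rank
definition was chosen because it is deterministic, always an observed
time, and free of interpolation choices; no standard quantile type is
mandated by the setting.

Conventions that matter numerically:

* events at exactly `tau` count as observed (closed window `[0, tau]`);
* at tied times, events are processed before censorings, and AE and CE
  occurring at the same time in different patients share the same
  at-risk set (standard survival conventions);
* step curves are right-continuous and evaluated at the largest jump at
  or before `tau`;
* the accounting-for-CE density transform returns 0 when no events of
  either type are observed (its `0/0` limit);
* a zero estimate is legal; downstream ratio code flags such units
  instead of taking `log(0)`.

Useful exact identities, all tested property-style: the AJE equals one
minus Kaplan-Meier when no CEs occur, equals the IP when no censoring
occurs before `tau`, and the AE and CE cumulative incidences always sum
to one minus the all-event Kaplan-Meier survival. On every dataset
`1 - KM >= AJE >= IP`.

## Comparison and meta-analysis

Each comparator estimator is divided by the gold-standard AJE per unit;
analysis happens on the log scale. Standard errors come from a
nonparametric bootstrap over patients within the unit (default
`B = 1000`; the evaluation time is re-derived inside each replicate when
a quantile rule is active, keeping the estimand consistent under
resampling). Replicates with a zero numerator or denominator are dropped
and counted, never imputed; confidence intervals are 2.5/97.5
percentiles of the replicate ratios. Units whose point estimate or gold
standard is zero, or that yield no usable bootstrap SE, are excluded
from meta-analysis listwise with a logged reason.

Pooling uses the normal-normal hierarchical model
`y_i ~ N(mu, se_i^2 + tau2)`, with `tau2` estimated by REML
(DerSimonian-Laird is available as a sensitivity option, and `"FE"`
constrains `tau2 = 0`, reproducing the closed-form inverse-variance
estimate). Wald confidence intervals on the log scale are the default;
the Knapp-Hartung adjustment is available. REML was preferred because
the study design names only the hierarchical model, and REML is the
least-biased standard choice for `tau2`; none of the qualitative
conclusions depend on it. The meta-regression centers covariates at
their means over the analysed units, so the exponentiated intercept is
the average ratio at mean covariate values; slopes are reported as
multiplicative changes per conventional increments (10 percentage points
of censoring or CEs, 0.1 of gold-standard AE probability, 1 year of
evaluation time). The percentage of CEs enters univariable models only:
it is strongly dependent on the censoring percentage and the AE
probability, and including it multivariably would make the coefficients
uninterpretable. A covariate that is constant across units is dropped
with slope 0 rather than producing a rank-deficient design.

## Frequency categories

AE probabilities map to the SmPC frequency categories very rare / rare /
uncommon / common / very common at `< 0.01%`, `< 0.1%`, `< 1%`, `< 10%`
and `>= 10%`. The lower cut-points are exclusive ("<") and exactly 10%
is *very common*, following the guideline's wording. Categories are
computed from unrounded estimates, never from 3-decimal displays.

## What the simulator emulates — and what it does not

`simulate_unit()` draws independent latent AE and CE times (exponential
by default, Weibull optionally), an independent exponential random
censoring time, and an administrative cut-off; the record is the
earliest of the three. CEs split into death vs. other CE with
probability 0.25/0.75 by default, reflecting that in time-to-first-AE
data deaths before AE are much rarer than other reasons AE recording
ends. `simulate_portfolio()` layers log-normal trial sizes (default
median 443, truncated to 200–7171), normal per-trial log-hazard
perturbations (default SD 0.3) and per-AE-type AE-hazard perturbations
(default SD 0.8, since AE types within a trial range from very rare to
very common), and emits the per-unit true cumulative incidence
`alpha/(alpha+beta) * (1 - exp(-(alpha+beta) * tau))` alongside the
data. The default baseline hazards (AE 2e-4/day, CE 1e-3/day, random
censoring 2e-4/day, administrative follow-up 900 days) were chosen once
so that the portfolio's aggregate censoring and CE fractions, follow-up
and gold-standard AE probabilities sit in the range reported for large
industry safety portfolios (roughly a third of patients censored, half
experiencing a CE first, median AE probability near 0.1).

The simulator deliberately omits features of real safety data: hazards
that change over time other than via the Weibull family, dependent
censoring, correlation between AE types within a patient, recurrent
AEs, and AEs recorded after treatment discontinuation. Passing tests on
simulated data therefore demonstrate correctness of the estimators and
of the comparison machinery under the stated generating mechanism — not
that any single estimator is unbiased for real trials, which is
precisely the question the AJE-vs-comparator ratios address.

All randomness flows from one master seed through a documented hierarchy
(portfolio → trial → unit, and a separate stream per bootstrap), so any
subset of a run is reproducible bit-for-bit.

## Problem sizes used in validation

The shipped validation suite works at sizes chosen to make Monte-Carlo
error negligible relative to the tolerances asserted: identity and
ordering properties on 500 random small datasets; brute-force risk-set
enumeration agreement to 1e-12 on 200 datasets of up to 8 patients;
constant-hazard consistency at n = 10,000 (AE hazard 0.001/day, CE
hazard 0.002/day, administrative censoring at 900 days, so the true
cumulative incidence is ~0.311 while the net-risk quantity one minus
Kaplan-Meier targets is ~0.593); goodness-of-fit of the simulator at
n = 100,000; and meta-analytic recovery of a planted average ratio of
1.2 with heterogeneity SD 0.05 across 150 units, averaged over 200
replications. The bundled analysis scripts use a 17-trial, 102-unit
portfolio with 200 bootstrap replicates per unit.

## Known limitations

* Two-group contrasts (relative risks, hazard ratios) are out of scope;
  everything here is one-sample.
* Single-estimator variances/CIs beyond the bootstrap of the log-ratio
  are not provided.
* No left truncation, no recurrent events, no MedDRA hierarchy handling.
* The exemplary-count reconstruction (`set_from_counts()`) fabricates
  event times; only count-based quantities computed from it (incidence
  proportion, event-state percentages) are meaningful.
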