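#!/usr/bin/env Rscript
# Stage 3: compare every estimator to the gold-standard Aalen-Johansen
# per unit: ratios with bootstrap standard errors of the log-ratios
# (B = 200 patient-level resamples per unit), and the composite-endpoint
# check that isolates the pure censoring effect.

library(aerisk)

seed <- 17L
sets <- read_analysis_sets("results/portfolio.csv")

ratios <- compare_units(sets, tau_rule = "max", B = 200, seed = seed)
write.csv(ratios, "results/ratios.csv", row.names = FALSE)

composite <- do.call(rbind, lapply(sets, function(s) {
  tau <- evaluation_time(s, "max")
  cmp <- composite_endpoint_analysis(s, tau)
  data.frame(trial_id = s$trial_id, ae_type = s$ae_type,
             ip_composite = cmp$ip_composite,
             one_minus_km_composite = cmp$one_minus_km_composite,
             ratio = cmp$ratio)
}))
rownames(composite) <- NULL
write.csv(composite, "results/composite_endpoint.csv", row.names = FALSE)

ok <- ratios[!ratios$excluded, ]
cat(sprintf("Ratio records: %d rows, %d usable (%d excluded: zero estimates or unusable bootstrap SE).\n",
            nrow(ratios), nrow(ok), sum(ratios$excluded)))
cat(sprintf("Degenerate bootstrap replicates dropped in total: %d.\n",
            sum(ratios$n_degenerate, na.rm = TRUE)))
cat("Median ratio vs gold-standard AJE, by estimator:\n")
print(round(tapply(ok$ratio, ok$estimator, median), 3))
cat(sprintf("Composite-endpoint IP/(1-KM) ratio: median %.3f, max %.3f (never above 1;\nthe shortfall is the downward bias attributable to censoring alone).\n",
            median(composite$ratio, na.rm = TRUE),
            max(composite$ratio, na.rm = TRUE)))
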