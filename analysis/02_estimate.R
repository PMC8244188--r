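#!/usr/bin/env Rscript
# Stage 2: evaluate all six one-sample estimators of the cumulative AE
# probability on every (trial, AE-type) unit, at the maximum follow-up
# time and at the 90% quantile of observed times, and summarise the
# observed event mix per unit.

library(aerisk)

sets <- read_analysis_sets("results/portfolio.csv")

estimates <- do.call(rbind, lapply(sets, function(s) {
  do.call(rbind, lapply(list("max", 0.9), function(rule) {
    tau <- evaluation_time(s, rule)
    cbind(trial_id = s$trial_id, ae_type = s$ae_type,
          tau_rule = as.character(rule), estimate_all(s, tau))
  }))
}))
rownames(estimates) <- NULL
write.csv(estimates, "results/estimates.csv", row.names = FALSE)

freq <- do.call(rbind, lapply(sets, function(s) {
  cnt <- count_events(s, evaluation_time(s, "max"))
  data.frame(trial_id = s$trial_id, ae_type = s$ae_type, n = cnt$n,
             t(cnt$proportions))
}))
rownames(freq) <- NULL
write.csv(freq, "results/event_frequencies.csv", row.names = FALSE)

cat(sprintf("Estimated %d units x 6 estimators x 2 tau rules.\n",
            length(sets)))
at_max <- estimates[estimates$tau_rule == "max", ]
med <- tapply(at_max$estimate, at_max$estimator, median)
cat("Median estimate at max follow-up, by estimator:\n")
print(round(med, 4))
cat("The gold-standard AJE sits between the incidence proportion (ignores\n")
cat("censoring, too low) and one minus Kaplan-Meier (censors competing\n")
cat("events, too high), as expected.\n")
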