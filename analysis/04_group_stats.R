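#!/usr/bin/env Rscript
# Step 4 — group-level statistics on the non-auditory measures.
#
# Pooled-variance two-sample t-tests (control vs stroke; df = n1 + n2 - 2
# with per-measure listwise deletion) for age, PTA3, PTA3 asymmetry and the
# cognitive / mood / vocabulary scores, and Spearman rank correlations of
# age and PTA3 with the assessment scores.

library(binlat)

cov <- read.csv(file.path("results", "covariates.csv"))
cov$group[cov$group != "control"] <- "stroke"

st <- group_stats(cov)
write.csv(st$t_tests, file.path("results", "stats_t.csv"), row.names = FALSE)
write.csv(st$correlations, file.path("results", "stats_cor.csv"),
          row.names = FALSE)

cat("two-sample t-tests (control minus stroke):\n")
print(st$t_tests, digits = 3)
cat("\nSpearman correlations:\n")
print(st$correlations, digits = 2)
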