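#!/usr/bin/env Rscript
# Cohort statistics: Shapiro-Wilk-routed correlations of dynamics with age
# (global transition probability; the four occurrence rates against the
# Bonferroni-adjusted alpha 0.05/4 = 0.0125), covariate-adjusted regression
# for Bonferroni-significant occurrence rates (age-adjusted MAC multiple,
# plus the nitrous flag for S1), and the 4x4 transition-probability
# correlation matrix under Benjamini-Hochberg at q = 0.20.

library(conndyn)

dyn <- read.csv("results/dynamics.csv")
meta <- read.csv("results/meta.csv")

report <- run_statistics(dyn, meta)
print(report)

out <- rbind(report$gtp, report$occurrence, report$transitions)
write.csv(out, "results/stats_report.csv", row.names = FALSE)
if (!is.null(report$regressions))
  write.csv(report$regressions, "results/regressions.csv",
            row.names = FALSE)

s1 <- report$occurrence[report$occurrence$variable == "occ_S1~age", ]
s4 <- report$occurrence[report$occurrence$variable == "occ_S4~age", ]
message(sprintf("S1 occupancy vs age: %s %.3f (p = %.4f)%s",
                s1$method, s1$coefficient, s1$p_value,
                ifelse(isTRUE(s1$significant), " *", "")))
message(sprintf("S4 occupancy vs age: %s %.3f (p = %.4f)%s",
                s4$method, s4$coefficient, s4$p_value,
                ifelse(isTRUE(s4$significant), " *", "")))
message(sprintf("BH critical p for the transition matrix: %g; %d/%d cells significant",
                report$fdr$critical_value, length(report$fdr$significant),
                nrow(report$transitions)))
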