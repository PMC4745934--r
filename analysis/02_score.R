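#!/usr/bin/env Rscript
# Apply the prognostic scores to the simulated cohort: GPS (CRP/albumin),
# PCPS (prealbumin/CRP), the low/high PCPS grouping, and PG-SGA triage bands.

library(pcps)

cohort <- read_cohort("results/cohort.csv")
scored <- score_cohort(cohort)
write.csv(as.data.frame(scored), "results/cohort_scored.csv", row.names = FALSE,
          na = "")

for (s in c("gps", "pcps")) {
  tab <- table(scored[[s]], useNA = "ifany")
  cat(s, "distribution:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
}
cat("PCPS high (score 2):",
    sprintf("%.0f%% of metastatic vs %.0f%% of nonmetastatic patients\n",
            100 * mean(scored$pcps[scored$metastatic] == 2, na.rm = TRUE),
            100 * mean(scored$pcps[!scored$metastatic] == 2, na.rm = TRUE)))
cat("wrote results/cohort_scored.csv\n")
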