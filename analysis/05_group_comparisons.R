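#!/usr/bin/env Rscript
# Group-comparison statistics on the scored cohort: biomarkers by metastasis
# group (pooled t-test for Gaussian markers, Mann-Whitney for skewed ones),
# scored PG-SGA across score categories (Kruskal-Wallis), and score-by-
# metastasis contingency tables (exact chi-square).

library(pcps)

scored <- read.csv("results/cohort_scored.csv", na.strings = "")

cat("-- biomarkers by metastasis group --\n")
rows <- list()
for (v in c("bmi", "albumin", "prealbumin", "transferrin", "tlc")) {
  cmp <- compare_means(scored[[v]], scored$metastatic, variable = v)
  cat(sprintf("%-12s mean diff %8.3f (95%% CI %8.3f to %8.3f)  p = %.3f\n",
              v, cmp$mean_diff, cmp$mean_diff_ci[1], cmp$mean_diff_ci[2],
              cmp$p_value))
  rows[[v]] <- data.frame(variable = v, method = cmp$method,
                          mean_diff = cmp$mean_diff,
                          ci_lower = cmp$mean_diff_ci[1],
                          ci_upper = cmp$mean_diff_ci[2], p = cmp$p_value)
}
for (v in c("crp", "pgsga_score")) {
  cmp <- compare_distributions(scored[[v]], scored$metastatic, variable = v)
  cat(sprintf("%-12s Mann-Whitney p = %.3f\n", v, cmp$p_value))
  rows[[v]] <- data.frame(variable = v, method = cmp$method, mean_diff = NA,
                          ci_lower = NA, ci_upper = NA, p = cmp$p_value)
}
write.csv(do.call(rbind, rows), "results/group_comparisons.csv",
          row.names = FALSE)

cat("\n-- scored PG-SGA across score categories (Kruskal-Wallis) --\n")
for (s in c("gps", "pcps")) {
  kw <- kruskal_wallis(scored$pgsga_score, scored[[s]], variable = s)
  cat(sprintf("PG-SGA by %s: H = %.2f, p = %.3f\n", s, kw$statistic, kw$p_value))
}

cat("\n-- score by metastasis (exact chi-square) --\n")
for (s in c("gps", "pcps")) {
  tab <- table(scored[[s]], ifelse(scored$metastatic, "metastatic",
                                   "nonmetastatic"))
  tab <- unclass(tab)[rowSums(tab) > 0, , drop = FALSE]
  cmp <- compare_categorical(tab, exact = TRUE, variable = s)
  pct <- round(cmp$group_summaries$column_percent)
  cat(sprintf("%s: X^2 = %.2f, exact p = %.3f; score-2 rate %d%% vs %d%%\n",
              s, cmp$statistic, cmp$p_value,
              pct[nrow(pct), "metastatic"], pct[nrow(pct), "nonmetastatic"]))
}
cat("wrote results/group_comparisons.csv\n")
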