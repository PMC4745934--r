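#!/usr/bin/env Rscript
# ROC analysis of prealbumin for predicting metastasis (lower values are the
# positive direction), Youden-index cut-off selection, and the diagnostic
# evaluation of the PCPS high/low grouping, including the Gini stump over
# the three score levels.

library(pcps)

scored <- read.csv("results/cohort_scored.csv", na.strings = "")

curve <- roc_curve(scored$prealbumin, scored$metastatic, "lower_is_positive")
cut <- youden_cutoff(curve)
cat(sprintf("prealbumin AUC %.2f (95%% CI %.2f-%.2f), n = %d+/%d-\n",
            curve$auc, curve$ci_auc[1], curve$ci_auc[2], curve$n_pos, curve$n_neg))
cat(sprintf("Youden cut-off %.3f mg/dL (J = %.3f; sen %.1f%%, spe %.1f%%)\n",
            cut$threshold, cut$youden_j, 100 * cut$sen, 100 * cut$spe))

eval_cm <- confusion_from_predictions(scored$pcps_binary == "high",
                                      scored$metastatic)
report <- diagnostic_report(eval_cm)
print(report)

stump <- stump_split(scored$pcps, scored$metastatic)
cat(sprintf("Gini-optimal PCPS split: {<=%d} vs {>%d} (impurity %.3f)\n",
            stump$split_point, stump$split_point, stump$gini))

out <- list(
  roc = list(auc = curve$auc, ci_auc = as.list(curve$ci_auc),
             n_pos = curve$n_pos, n_neg = curve$n_neg,
             thresholds = curve$thresholds, sen = curve$sen, fpr = curve$fpr),
  cutoff = list(threshold = cut$threshold, youden_j = cut$youden_j,
                sen = cut$sen, spe = cut$spe),
  pcps_evaluation = lapply(unclass(report)[-1], unclass),
  stump = list(split_point = stump$split_point, gini = stump$gini)
)
jsonlite::write_json(out, "results/roc_cutoff.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE, force = TRUE)
cat("wrote results/roc_cutoff.json\n")
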