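#!/usr/bin/env Rscript
# Classification comparison: nine game features versus MoCA as
# cross-validated elastic-net predictors of DGI dichotomized at the
# sample median. Writes out-of-fold scores, ROC points for both arms, and
# a summary with accuracies, exact binomial tests against a coin flip,
# AUCs, and DeLong's one-sided paired AUC comparison.
#
# Usage: Rscript analysis/04_classification.R [--seed INT] [--cohort DIR]
#                                             [--out DIR] [--repeats INT]

suppressPackageStartupMessages(library(gglearn))

args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i)) default else args[i + 1]
}
seed <- as.integer(arg("--seed", "1"))
cohort_dir <- arg("--cohort", "results/cohort")
out <- arg("--out", "results")
repeats <- as.integer(arg("--repeats", "10"))

features <- read.csv(file.path(out, "features.csv"))
clinical <- read_clinical(file.path(cohort_dir, "clinical.csv"))

cmp <- compare_predictors(features, clinical,
                          cv_config(repeats = repeats, seed = seed))
print(cmp)

write.csv(data.frame(patient_id = sort(features$patient_id),
                     label = cmp$labels, gg_score = cmp$gg$scores,
                     moca_score = cmp$moca$scores),
          file.path(out, "oof_scores.csv"), row.names = FALSE)
write.csv(cmp$gg$roc, file.path(out, "roc_gg.csv"), row.names = FALSE)
write.csv(cmp$moca$roc, file.path(out, "roc_moca.csv"), row.names = FALSE)

summary_lines <- c(
  sprintf("seed: %d  cv repeats: %d  patients: %d", seed, repeats, cmp$n),
  sprintf("GG accuracy: %.1f%% (binomial p = %.3g), AUC %.3f",
          100 * cmp$gg$accuracy, cmp$gg$binomial_p, cmp$gg$auc),
  sprintf("MoCA accuracy: %.1f%% (binomial p = %.3g), AUC %.3f",
          100 * cmp$moca$accuracy, cmp$moca$binomial_p, cmp$moca$auc),
  sprintf("DeLong one-sided p (GG > MoCA): %.3g", cmp$delong$p_value))
writeLines(summary_lines, file.path(out, "classification_summary.txt"))
cat("wrote", file.path(out, "classification_summary.txt"), "\n")
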