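#!/usr/bin/env Rscript
# Fit the Bernoulli learning-curve model to every patient-stage series of
# the simulated cohort and assemble the nine-variable feature table
# (beta1..3, gamma1..3, tbar1..3). Reports cohort-level means/sds of the
# estimates next to the generating population values, i.e. how much the
# short 5-trial stages shrink the estimates toward the prior.
#
# Usage: Rscript analysis/02_fit_learning_curves.R [--cohort DIR] [--out DIR]

suppressPackageStartupMessages(library(gglearn))

args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i)) default else args[i + 1]
}
cohort_dir <- arg("--cohort", "results/cohort")
out <- arg("--out", "results")

trials <- read_trials(file.path(cohort_dir, "trials.csv"))
features <- fit_cohort(trials)
dir.create(out, showWarnings = FALSE, recursive = TRUE)
write.csv(features, file.path(out, "features.csv"), row.names = FALSE)

cat(sprintf("fitted %d patients\n", nrow(features)))
cols <- c(paste0("beta", 1:3), paste0("gamma", 1:3), paste0("tbar", 1:3))
summ <- rbind(mean = colMeans(features[cols]),
              sd = apply(features[cols], 2, sd))
print(round(summ, 2))

truth_path <- file.path(cohort_dir, "truth.csv")
if (file.exists(truth_path)) {
  truth <- read.csv(truth_path)
  for (s in 1:3) {
    tg <- truth$gamma_true[truth$stage == s]
    cat(sprintf("stage %d: cor(gamma_hat, gamma_true) = %.2f\n", s,
                cor(features[[paste0("gamma", s)]], tg)))
  }
}
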