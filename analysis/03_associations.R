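#!/usr/bin/env Rscript
# Association analyses: the ten-row polyserial/polychoric correlation
# table of DGI against MoCA and the nine game variables, and the
# proportional-odds models for DGI (nine-predictor game model and
# single-predictor MoCA model).
#
# Usage: Rscript analysis/03_associations.R [--cohort DIR] [--out DIR]

suppressPackageStartupMessages(library(gglearn))

args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i)) default else args[i + 1]
}
cohort_dir <- arg("--cohort", "results/cohort")
out <- arg("--out", "results")

features <- read.csv(file.path(out, "features.csv"))
clinical <- read_clinical(file.path(cohort_dir, "clinical.csv"))

assoc <- association_table(features, clinical)
write.csv(assoc, file.path(out, "associations.csv"), row.names = FALSE)
cat("correlations with DGI:\n")
print(transform(assoc, estimate = round(estimate, 2),
                p_value = signif(p_value, 2)))
top <- assoc$variable[which.max(abs(assoc$estimate))]
cat(sprintf("most strongly correlated variable: %s\n\n", top))

dat <- merge(features, clinical, by = "patient_id")
cols <- c(paste0("beta", 1:3), paste0("gamma", 1:3), paste0("tbar", 1:3))
ord_gg <- proportional_odds_fit(as.matrix(dat[cols]), dat$dgi_total)
ord_moca <- proportional_odds_fit(
  matrix(dat$moca_total, ncol = 1, dimnames = list(NULL, "moca")),
  dat$dgi_total)

cat("proportional-odds model, DGI ~ nine game variables:\n")
print(ord_gg)
cat(sprintf("\nDGI ~ MoCA: coefficient %.3f (p = %.2g)\n",
            ord_moca$coefficients[1], ord_moca$p_values[1]))
write.csv(data.frame(variable = names(ord_gg$coefficients),
                     coefficient = unname(ord_gg$coefficients),
                     p_value = unname(ord_gg$p_values)),
          file.path(out, "ordinal_gg.csv"), row.names = FALSE)
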