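# End-to-end orchestration: simulate -> fit -> associate -> classify.
# The numbered scripts under analysis/ are thin drivers over these
# functions; tests and the acceptance script call them directly.

#' Read a trials CSV
#'
#' Expected columns: `patient_id`, `stage` (1-3), `trial_index` (1-based
#' within stage), `outcome` (0/1), `response_time_s`. Malformed rows are
#' reported with their row numbers.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("trials file not found: ", path, call. = FALSE)
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(trials)
  trials
}

#' Read a clinical CSV
#'
#' Expected columns: `patient_id`, `dgi_total` (0-24), `moca_total`
#' (0-30); further covariate columns pass through untouched.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path))
    stop("clinical file not found: ", path, call. = FALSE)
  clin <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("patient_id", "dgi_total", "moca_total"), names(clin))
  if (length(miss))
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(clin$dgi_total < 0 | clin$dgi_total > 24, na.rm = TRUE))
    stop("dgi_total outside 0..24", call. = FALSE)
  if (any(clin$moca_total < 0 | clin$moca_total > 30, na.rm = TRUE))
    stop("moca_total outside 0..30", call. = FALSE)
  clin
}

check_key_consistency <- function(features, clinical) {
  orphans_f <- setdiff(features$patient_id, clinical$patient_id)
  orphans_c <- setdiff(clinical$patient_id, features$patient_id)
  if (length(orphans_f) || length(orphans_c))
    stop("patient_id mismatch between feature and clinical tables; ",
         "orphans: ",
         paste(utils::head(c(orphans_f, orphans_c), 10), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Run the full Goalkeeper Game analysis pipeline
#'
#' Generates (or loads) a cohort, fits the learning-curve model to every
#' patient-stage, computes the DGI association table and proportional-odds
#' models, and runs the GG-versus-MoCA classification comparison. All
#' randomness derives deterministically from the single `seed`.
#'
#' @param seed Global integer seed.
#' @param cohort Optional pre-generated `synthetic_cohort` or list with
#'   `trials` and `clinical` data frames; by default a cohort is simulated
#'   from `config`.
#' @param config A [cohort_config()] used when simulating.
#' @param cv A [cv_config()]; its seed is overridden by the derived
#'   prediction seed.
#' @param out_dir Optional directory; when given, all tables are written
#'   as CSV together with a run manifest and a human-readable summary.
#'
#' @return A list: `cohort`, `features`, `associations`, `ordinal_gg`,
#'   `ordinal_moca`, `comparison`.
#' @export
run_gg_pipeline <- function(seed = 1L, cohort = NULL,
                            config = cohort_config(),
                            cv = cv_config(), out_dir = NULL) {
  if (is.null(cohort)) {
    config$seed <- derive_seed(seed, "simulate")
    cohort <- generate_cohort(config)
  }
  features <- fit_cohort(cohort$trials)
  check_key_consistency(features, cohort$clinical)
  assoc <- association_table(features, cohort$clinical)

  dat <- merge(features, cohort$clinical, by = "patient_id")
  feat_cols <- c(paste0("beta", 1:3), paste0("gamma", 1:3),
                 paste0("tbar", 1:3))
  ord_gg <- proportional_odds_fit(as.matrix(dat[, feat_cols]),
                                  dat$dgi_total)
  ord_moca <- proportional_odds_fit(matrix(dat$moca_total, ncol = 1,
                                           dimnames = list(NULL, "moca")),
                                    dat$dgi_total)
  cv$seed <- derive_seed(seed, "prediction")
  comparison <- compare_predictors(features, cohort$clinical, cv)

  out <- list(cohort = cohort, features = features, associations = assoc,
              ordinal_gg = ord_gg, ordinal_moca = ord_moca,
              comparison = comparison, seed = seed)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(res$cohort, "synthetic_cohort"))
    write_cohort(res$cohort, out_dir)
  utils::write.csv(res$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(res$associations, file.path(out_dir, "associations.csv"),
                   row.names = FALSE)
  ord <- data.frame(variable = names(res$ordinal_gg$coefficients),
                    coefficient = unname(res$ordinal_gg$coefficients),
                    p_value = unname(res$ordinal_gg$p_values))
  utils::write.csv(ord, file.path(out_dir, "ordinal_gg.csv"),
                   row.names = FALSE)
  cmp <- res$comparison
  utils::write.csv(
    data.frame(patient_id = res$features$patient_id[
                 res$features$patient_id %in% res$cohort$clinical$patient_id],
               label = cmp$labels, gg_score = cmp$gg$scores,
               moca_score = cmp$moca$scores),
    file.path(out_dir, "oof_scores.csv"), row.names = FALSE)
  utils::write.csv(cmp$gg$roc, file.path(out_dir, "roc_gg.csv"),
                   row.names = FALSE)
  utils::write.csv(cmp$moca$roc, file.path(out_dir, "roc_moca.csv"),
                   row.names = FALSE)
  summary_lines <- c(
    sprintf("seed: %d", res$seed),
    sprintf("patients analyzed: %d", cmp$n),
    sprintf("GG accuracy: %.1f%% (binomial p = %.3g)",
            100 * cmp$gg$accuracy, cmp$gg$binomial_p),
    sprintf("MoCA accuracy: %.1f%% (binomial p = %.3g)",
            100 * cmp$moca$accuracy, cmp$moca$binomial_p),
    sprintf("AUC: GG %.3f, MoCA %.3f", cmp$gg$auc, cmp$moca$auc),
    sprintf("DeLong one-sided p (GG > MoCA): %.3g", cmp$delong$p_value),
    sprintf("top correlated variable: %s (%.2f)",
            res$associations$variable[which.max(abs(res$associations$estimate))],
            res$associations$estimate[which.max(abs(res$associations$estimate))]))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}
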