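# Classification comparison: the nine Goalkeeper Game variables versus the
# single MoCA score as cross-validated predictors of dichotomized DGI.
# Elastic-net logistic regression with penalty strength chosen by inner
# cross-validation on each training fold; evaluation by out-of-fold
# accuracy, exact binomial test against a coin flip, ROC/AUC, and DeLong's
# paired comparison of correlated AUCs.

#' Cross-validation configuration for the classifier comparison
#'
#' @param folds Outer folds (default 10, stratified by class).
#' @param repeats Repetitions of the whole cross-validation (default 10);
#'   accuracies are averaged over repeats and per-patient scores are the
#'   mean out-of-fold probability.
#' @param alpha Elastic-net mixing parameter in `[0, 1]` (default 0.5).
#' @param inner_folds Folds of the inner penalty-selection CV (default 5).
#' @param n_lambda Length of the penalty grid (default 50).
#' @param seed Integer seed governing fold assignment and inner CV.
#'
#' @return A `cv_config` list.
#' @export
cv_config <- function(folds = 10, repeats = 10, alpha = 0.5,
                      inner_folds = 5, n_lambda = 50, seed = 1L) {
  stopifnot(folds >= 2, repeats >= 1, alpha >= 0, alpha <= 1,
            inner_folds >= 3)
  structure(list(folds = folds, repeats = repeats, alpha = alpha,
                 inner_folds = inner_folds, n_lambda = n_lambda,
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Dichotomize DGI at the sample median
#'
#' Label 1 for scores strictly above the sample median; ties at the median
#' go to the lower class ("above the median" read strictly).
#'
#' @param dgi Numeric vector of ordinal DGI totals.
#'
#' @return Integer 0/1 vector with attribute `class_balance`.
#' @export
#'
#' @examples
#' dichotomize_dgi(c(10, 20, 30))
dichotomize_dgi <- function(dgi) {
  if (length(dgi) == 0) stop("empty DGI vector", call. = FALSE)
  med <- stats::median(dgi)
  labels <- as.integer(dgi > med)
  if (length(unique(labels)) < 2)
    stop("degenerate labels: all DGI values fall on one side of the median",
         call. = FALSE)
  attr(labels, "class_balance") <- c(below_or_at = sum(labels == 0),
                                     above = sum(labels == 1))
  labels
}

# Stratified fold assignment: within each class, shuffle and deal into
# folds round-robin. Returns an integer fold id per observation.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    if (length(idx) < k && length(idx) < 1)
      stop("class absent from data; cannot stratify", call. = FALSE)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Fit elastic-net logistic regression on a training fold with the penalty
# chosen by inner CV, and return predicted probabilities for newx. With a
# single predictor the penalty is inert and a plain logistic fit is used.
fit_predict_enet <- function(x_train, y_train, x_new, config,
                             inner_seed = config$seed) {
  if (ncol(x_train) == 1L) {
    df <- data.frame(y = y_train, x = x_train[, 1])
    fit <- suppressWarnings(stats::glm(y ~ x, binomial, df))
    return(unname(stats::predict(fit, data.frame(x = x_new[, 1]),
                                 type = "response")))
  }
  foldid <- with_seed(inner_seed, stratified_folds(y_train,
                                                   config$inner_folds))
  cvfit <- glmnet::cv.glmnet(x_train, y_train, family = "binomial",
                             alpha = config$alpha, foldid = foldid,
                             nlambda = config$n_lambda,
                             standardize = TRUE)
  drop(stats::predict(cvfit, newx = x_new, s = "lambda.min",
                      type = "response"))
}

#' Repeated stratified cross-validation of an elastic-net classifier
#'
#' Out-of-fold probabilities from `repeats` runs of `folds`-fold stratified
#' cross-validation; within each training fold the penalty strength is
#' selected by inner cross-validation only on that fold. Accuracy is the
#' fraction of correct out-of-fold predictions at probability threshold
#' 0.5, averaged over repeats.
#'
#' @param X Predictor matrix (patients in rows); standardized internally
#'   per training fold by the elastic-net fit.
#' @param y Binary 0/1 labels.
#' @param config A [cv_config()].
#'
#' @return A `classifier_evaluation` list: `scores` (per-patient mean
#'   out-of-fold probability), `score_matrix` (patients x repeats),
#'   `predicted` (labels at 0.5 from mean scores), `accuracy`,
#'   `correct_count` (rounded to the nearest whole prediction for the
#'   binomial test), `binomial_p`, `roc`, `auc`, `labels`, `fold_ids`.
#' @export
cv_elastic_net <- function(X, y, config = cv_config()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(length(y) == nrow(X), all(y %in% 0:1))
  if (min(table(y)) < config$folds)
    stop("a class has fewer members than folds; stratification impossible",
         call. = FALSE)
  n <- nrow(X)
  score_mat <- matrix(NA_real_, n, config$repeats)
  acc <- numeric(config$repeats)
  # all outer partitions are drawn up front so that two classifiers run
  # with the same config see byte-identical folds regardless of how much
  # randomness their inner fits consume
  fold_ids <- with_seed(config$seed, vapply(
    seq_len(config$repeats), function(r) stratified_folds(y, config$folds),
    integer(n)))
  for (r in seq_len(config$repeats)) {
    fold <- fold_ids[, r]
    for (f in seq_len(config$folds)) {
      test <- fold == f
      inner_seed <- (config$seed + 7919 * r + 104729 * f) %% 2147483629
      score_mat[test, r] <- fit_predict_enet(
        X[!test, , drop = FALSE], y[!test], X[test, , drop = FALSE],
        config, inner_seed)
    }
    acc[r] <- mean((score_mat[, r] > 0.5) == (y == 1))
  }
  scores <- rowMeans(score_mat)
  accuracy <- mean(acc)
  correct <- round(accuracy * n)
  roc <- roc_and_auc(scores, y)
  structure(list(
    scores = scores, score_matrix = score_mat,
    predicted = as.integer(scores > 0.5),
    accuracy = accuracy, correct_count = correct,
    binomial_p = binomial_vs_chance(correct, n),
    roc = roc$roc, auc = roc$auc,
    labels = y, fold_ids = fold_ids, config = config),
    class = "classifier_evaluation")
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat(sprintf(
    "cross-validated classifier: accuracy %.1f%% (binomial p = %.3g), AUC %.3f\n",
    100 * x$accuracy, x$binomial_p, x$auc))
  invisible(x)
}

#' Exact binomial test of a classifier against a coin flip
#'
#' @param correct Number of correct out-of-fold predictions.
#' @param n Number of predictions.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#'
#' @return The p-value of the exact binomial test against success
#'   probability one half.
#' @export
binomial_vs_chance <- function(correct, n, alternative = "two.sided") {
  if (n == 0) stop("n must be positive", call. = FALSE)
  stopifnot(correct >= 0, correct <= n)
  stats::binom.test(correct, n, p = 0.5, alternative = alternative)$p.value
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every distinct score threshold; the AUC equals the Mann-Whitney
#' pair-counting statistic with half credit for ties (computed via average
#' ranks), so the two routes agree exactly.
#'
#' @param scores Numeric classifier scores (higher means class 1).
#' @param labels 0/1 labels.
#'
#' @return List with `roc` (data frame `fpr`, `tpr`, monotone from (0,0)
#'   to (1,1)) and `auc`.
#' @export
roc_and_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels == 1] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), 0)
  roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(roc = roc, auc = auc)
}

# DeLong placement values: for each positive case, the fraction of
# negatives it outranks (ties half), and vice versa.
placement_values <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), 0)
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), 0)
  list(v10 = v10, v01 = v01)
}

#' DeLong comparison of two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two classifiers scored on the
#' same patients, using the DeLong placement-value covariance estimate.
#'
#' @param scores_a,scores_b Paired score vectors for the two classifiers.
#' @param labels Common 0/1 labels.
#' @param alternative `"greater"` (one-sided, A > B; default, matching the
#'   usual use of testing whether a richer predictor beats a baseline),
#'   `"less"`, or `"two.sided"`.
#'
#' @return List: `auc_a`, `auc_b`, `auc_diff`, `variance`, `p_value`,
#'   `degenerate` (TRUE when the estimated variance of the difference is
#'   zero, in which case the p-value is reported as NA).
#' @export
delong_compare <- function(scores_a, scores_b, labels,
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  labels <- as.integer(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  pa <- placement_values(scores_a, labels)
  pb <- placement_values(scores_b, labels)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- auc_a - auc_b
  if (v <= 0) {
    return(list(auc_a = auc_a, auc_b = auc_b, auc_diff = d, variance = v,
                p_value = NA_real_, degenerate = TRUE))
  }
  z <- d / sqrt(v)
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(-abs(z)))
  list(auc_a = auc_a, auc_b = auc_b, auc_diff = d, variance = v,
       p_value = p, degenerate = FALSE)
}

#' Compare Goalkeeper Game features and MoCA as predictors of dichotomized DGI
#'
#' Runs the full classification comparison: DGI is dichotomized at the
#' sample median, then the nine-feature elastic-net classifier and the
#' single-score MoCA classifier are evaluated with identical fold
#' assignments, and their AUCs compared one-sided by DeLong's test
#' (alternative: the feature-based AUC is greater).
#'
#' @param features Feature table from [fit_cohort()].
#' @param clinical Clinical table with `patient_id`, `dgi_total`,
#'   `moca_total`.
#' @param config A [cv_config()].
#'
#' @return A `predictor_comparison` list: `gg` and `moca`
#'   (`classifier_evaluation` objects), `delong`, `labels`, `n`.
#' @export
compare_predictors <- function(features, clinical, config = cv_config()) {
  dat <- merge(features, clinical, by = "patient_id")
  feat_cols <- c(paste0("beta", 1:3), paste0("gamma", 1:3),
                 paste0("tbar", 1:3))
  cc <- stats::complete.cases(dat[, c(feat_cols, "moca_total", "dgi_total")])
  dat <- dat[cc, ]
  y <- dichotomize_dgi(dat$dgi_total)
  gg <- cv_elastic_net(as.matrix(dat[, feat_cols]), y, config)
  moca <- cv_elastic_net(matrix(dat$moca_total, ncol = 1,
                                dimnames = list(NULL, "moca_total")),
                         y, config)
  stopifnot(identical(gg$fold_ids, moca$fold_ids))  # same partitions
  structure(list(
    gg = gg, moca = moca,
    delong = delong_compare(gg$scores, moca$scores, y, "greater"),
    labels = y, n = length(y)),
    class = "predictor_comparison")
}

#' @export
print.predictor_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("GG features: accuracy %.1f%% (binomial p = %.3g), AUC %.3f\n",
           "MoCA:        accuracy %.1f%% (binomial p = %.3g), AUC %.3f\n",
           "DeLong one-sided (GG > MoCA): p = %.3g\n"),
    100 * x$gg$accuracy, x$gg$binomial_p, x$gg$auc,
    100 * x$moca$accuracy, x$moca$binomial_p, x$moca$auc,
    x$delong$p_value))
  invisible(x)
}
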