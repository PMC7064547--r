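# Dichotomization, cross-validated elastic net, ROC/AUC and DeLong
# machinery, cross-checked against pair enumeration and pROC.

test_that("median dichotomization sends ties to the lower class", {
  expect_identical(as.integer(dichotomize_dgi(c(10, 20, 30))), c(0L, 0L, 1L))
  y <- dichotomize_dgi(c(1, 2, 3, 4, 5))
  expect_identical(as.integer(y), c(0L, 0L, 0L, 1L, 1L))
  expect_equal(unname(attr(y, "class_balance")), c(3, 2))
  expect_error(dichotomize_dgi(c(5, 5, 5)), "degenerate")
  expect_error(dichotomize_dgi(numeric(0)), "empty")
})

test_that("AUC equals pair counting and the documented 4-point example", {
  ex <- roc_and_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(ex$auc, 0.75, tolerance = 1e-12)

  set.seed(31)
  scores <- round(rnorm(60), 1)  # coarse scores force ties
  labels <- rbinom(60, 1, 0.5)
  mine <- roc_and_auc(scores, labels)
  expect_equal(mine$auc, auc_pair_count(scores, labels), tolerance = 1e-12)
  skip_if_not_installed("pROC")
  ref <- pROC::auc(pROC::roc(labels, scores, quiet = TRUE))
  expect_equal(mine$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("ROC is monotone from (0,0) to (1,1) and invariant to monotone transforms", {
  set.seed(32)
  scores <- runif(80)
  labels <- rbinom(80, 1, 0.5)
  r <- roc_and_auc(scores, labels)
  expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
  expect_equal(tail(r$roc$fpr, 1), 1); expect_equal(tail(r$roc$tpr, 1), 1)
  expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))

  r2 <- roc_and_auc(exp(3 * scores), labels)
  expect_equal(r$auc, r2$auc, tolerance = 1e-12)
  expect_equal(r$roc$tpr, r2$roc$tpr)

  expect_equal(roc_and_auc(labels + 0.0, labels)$auc, 1)
  expect_error(roc_and_auc(scores, rep(1, 80)), "classes")
})

test_that("exact binomial test against chance behaves at the anchors", {
  expect_gt(binomial_vs_chance(37, 74), 0.9)
  expect_equal(binomial_vs_chance(74, 74), 2 * 0.5^74, tolerance = 1e-12)
  # direct pmf summation oracle for the two-sided exact test
  p48 <- sum(dbinom(0:74, 74, 0.5)[dbinom(0:74, 74, 0.5) <=
                                     dbinom(48, 74, 0.5) + 1e-12])
  expect_equal(binomial_vs_chance(48, 74), p48, tolerance = 1e-10)
  expect_error(binomial_vs_chance(0, 0), "positive")
})

test_that("DeLong variance matches the brute-force placement oracle", {
  set.seed(33)
  for (rep in 1:5) {
    labels <- c(rep(1, 5), rep(0, 5))
    a <- round(rnorm(10), 1)
    b <- round(a + rnorm(10), 1)
    mine <- delong_compare(a, b, labels, "two.sided")
    brute <- delong_brute(a, b, labels)
    expect_equal(mine$auc_diff, brute$auc_a - brute$auc_b,
                 tolerance = 1e-12)
    expect_lt(abs(mine$variance - brute$variance), 1e-10)
  }
})

test_that("DeLong agrees with pROC and flags degenerate comparisons", {
  skip_if_not_installed("pROC")
  set.seed(34)
  labels <- rbinom(60, 1, 0.5)
  a <- rnorm(60) + labels
  b <- rnorm(60) + 0.5 * labels
  mine <- delong_compare(a, b, labels, "two.sided")
  ref <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE),
                        pROC::roc(labels, b, quiet = TRUE),
                        method = "delong")
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)

  same <- delong_compare(a, a, labels)
  expect_equal(same$auc_diff, 0)
  expect_true(same$degenerate)
  expect_true(is.na(same$p_value))
})

test_that("cross-validated elastic net finds a perfect separator", {
  set.seed(35)
  n <- 74
  y <- rep(0:1, length.out = n)
  X <- cbind(sep = y + rnorm(n, sd = 0.05),
             matrix(rnorm(n * 8), n, 8))
  ev <- cv_elastic_net(X, y, cv_config(repeats = 2, seed = 1))
  expect_gte(ev$accuracy, 0.95)
  expect_gte(ev$auc, 0.99)
  expect_lt(ev$binomial_p, 1e-10)
})

test_that("stratification fails loudly when a class is too small", {
  y <- c(rep(0, 70), rep(1, 4))
  X <- matrix(rnorm(74 * 3), 74, 3)
  expect_error(cv_elastic_net(X, y, cv_config(folds = 10)), "stratification")
})

test_that("the two arms of the comparison share fold assignments", {
  coh <- generate_cohort(cohort_config(n_patients = 40, seed = 61))
  feats <- fit_cohort(coh$trials, quad = fast_quad())
  cmp <- compare_predictors(feats, coh$clinical,
                            cv_config(repeats = 2, seed = 4))
  expect_identical(cmp$gg$fold_ids, cmp$moca$fold_ids)
  expect_equal(length(cmp$gg$scores), cmp$n)
  expect_true(all(cmp$gg$scores >= 0 & cmp$gg$scores <= 1))
  # removing one patient regenerates without error
  cmp2 <- compare_predictors(feats[-1, ],
                             coh$clinical[coh$clinical$patient_id !=
                                            feats$patient_id[1], ],
                             cv_config(repeats = 2, seed = 4))
  expect_equal(cmp2$n, cmp$n - 1)
})

test_that("cross-validation is reproducible under a fixed seed", {
  set.seed(36)
  n <- 60
  y <- rep(0:1, each = 30)
  X <- matrix(rnorm(n * 9), n, 9)
  e1 <- cv_elastic_net(X, y, cv_config(repeats = 2, seed = 42))
  e2 <- cv_elastic_net(X, y, cv_config(repeats = 2, seed = 42))
  expect_identical(e1$scores, e2$scores)
  expect_identical(e1$accuracy, e2$accuracy)
})
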