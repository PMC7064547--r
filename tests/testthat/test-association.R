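# Polyserial/polychoric estimators and the proportional-odds fitter,
# cross-checked against mvtnorm, MASS::polr and ordinary logistic
# regression.

test_that("bivariate normal CDF matches mvtnorm", {
  skip_if_not_installed("mvtnorm")
  set.seed(2)
  h <- rnorm(20); k <- rnorm(20)
  for (rho in c(-0.8, -0.2, 0.39, 0.7)) {
    ref <- sapply(seq_along(h), function(i)
      mvtnorm::pmvnorm(upper = c(h[i], k[i]),
                       corr = matrix(c(1, rho, rho, 1), 2)))
    expect_lt(max(abs(gglearn:::bvn_cdf(h, k, rho) - ref)), 1e-10)
  }
})

test_that("polyserial estimator recovers the latent correlation", {
  set.seed(14)
  n <- 2000
  x <- rnorm(n)
  z <- 0.39 * x + sqrt(1 - 0.39^2) * rnorm(n)
  y <- cut_latent_ordinal(z, 0, 24, 19, 4)
  res <- polyserial_correlation(x, y)
  expect_lt(abs(res$estimate - 0.39), 0.07)
  expect_lt(res$p_value, 1e-6)

  # invariance to strictly increasing relabeling of the ordinal
  res2 <- polyserial_correlation(x, y^3 + 10)
  expect_equal(res$estimate, res2$estimate, tolerance = 1e-10)

  # independent pair: estimate near zero
  res0 <- polyserial_correlation(rnorm(n), y)
  expect_lt(abs(res0$estimate), 0.05)
})

test_that("polyserial beats Pearson on a binary-cut latent", {
  set.seed(15)
  n <- 5000
  x <- rnorm(n)
  z <- 0.5 * x + sqrt(0.75) * rnorm(n)
  y <- as.integer(z > 0.3)
  res <- polyserial_correlation(x, y)
  expect_lt(abs(res$estimate - 0.5), 0.05)
  expect_gt(abs(res$estimate), abs(cor(x, y)) + 0.05)
})

test_that("polychoric estimator recovers and flags perfect association", {
  set.seed(16)
  n <- 2000
  z <- rnorm(n)
  y1 <- cut_latent_ordinal(0.2 * z + sqrt(1 - 0.04) * rnorm(n),
                           21, 30, 24.6, 3)
  y2 <- cut_latent_ordinal(z, 0, 24, 19, 4)
  res <- polychoric_correlation(y1, y2)
  expect_lt(abs(res$estimate - 0.20), 0.08)
  expect_equal(res$estimate,
               polychoric_correlation(2 * y1 + 3, exp(y2 / 10))$estimate,
               tolerance = 1e-10)

  same <- polychoric_correlation(y2, y2)
  expect_gt(same$estimate, 0.97)
  expect_true(same$boundary)
  expect_error(polychoric_correlation(rep(1, 100), y2[1:100]), "categories")
  expect_error(polyserial_correlation(rep(1, 100), y2[1:100]), "constant")
})

test_that("proportional-odds fitter matches MASS::polr on 4 categories", {
  set.seed(17)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta <- 1.2 * x1 - 0.5 * x2
  y <- findInterval(eta + rlogis(n), c(-1, 0.5, 2)) + 1
  fit <- proportional_odds_fit(cbind(x1 = x1, x2 = x2), y)
  ref <- MASS::polr(factor(y, ordered = TRUE) ~ x1 + x2, Hess = TRUE)
  expect_lt(max(abs(fit$coefficients - coef(ref))), 1e-4)
  expect_lt(max(abs(fit$zeta - ref$zeta)), 1e-4)
  expect_true(all(diff(fit$zeta) > 0))
  expect_true(fit$converged)
  # Wald p-values against polr's t statistics
  ref_p <- 2 * pnorm(-abs(summary(ref)$coefficients[1:2, "t value"]))
  expect_equal(unname(fit$p_values), unname(ref_p), tolerance = 1e-3)
})

test_that("two-category fit reduces to logistic regression", {
  set.seed(18)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- as.integer(0.8 * x1 - 0.3 * x2 + rlogis(n) > 0)
  fit <- proportional_odds_fit(cbind(x1 = x1, x2 = x2), y)
  ref <- glm(y ~ x1 + x2, binomial)
  expect_lt(max(abs(fit$coefficients - coef(ref)[2:3])), 1e-6)
  expect_lt(abs(fit$zeta[1] + coef(ref)[1]), 1e-6)

  # single binary predictor: coefficient is the 2x2 log odds ratio
  g <- rbinom(n, 1, 0.5)
  yb <- rbinom(n, 1, plogis(-0.4 + 1.1 * g))
  tab <- table(g, yb)
  lor <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
  fitb <- proportional_odds_fit(matrix(g, ncol = 1), yb)
  expect_lt(abs(fitb$coefficients[1] - lor), 1e-6)
})

test_that("fitter recovers a strong gamma3 effect from its own generating model", {
  set.seed(19)
  n <- 4000
  x <- rnorm(n)  # standardized gamma3
  zeta <- seq(-10, 10, length.out = 24)
  y <- findInterval(5.28 * x + rlogis(n), zeta)
  fit <- proportional_odds_fit(matrix(x, ncol = 1, dimnames =
                                        list(NULL, "gamma3")), y)
  expect_lt(abs(fit$coefficients[1] - 5.28) / 5.28, 0.10)
})

test_that("association table has the published layout", {
  coh <- generate_cohort(cohort_config(n_patients = 40, seed = 23))
  feats <- fit_cohort(coh$trials, quad = fast_quad())
  tab <- association_table(feats, coh$clinical)
  expect_equal(tab$variable,
               c("moca", "beta1", "gamma1", "tbar1", "beta2", "gamma2",
                 "tbar2", "beta3", "gamma3", "tbar3"))
  expect_equal(tab$method, c("polychoric", rep("polyserial", 9)))
  expect_true(all(abs(tab$estimate) < 1))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
})

test_that("gamma3 dominates the game-variable correlations at scale", {
  # large cohort so estimation noise does not mask the construction
  coh <- generate_cohort(cohort_config(n_patients = 600, seed = 29))
  feats <- fit_cohort(coh$trials, quad = fast_quad())
  tab <- association_table(feats, coh$clinical)
  gg <- tab[tab$variable != "moca", ]
  expect_equal(gg$variable[which.max(abs(gg$estimate))], "gamma3")
  expect_gt(gg$estimate[gg$variable == "gamma3"], 0)

  # and at the truth level gamma3 tops the whole table including MoCA
  truth_g3 <- coh$truth$gamma_true[coh$truth$stage == 3]
  ps <- polyserial_correlation(truth_g3, coh$clinical$dgi_total)
  expect_gt(abs(ps$estimate),
            max(abs(tab$estimate[tab$variable != "gamma3"])))
})
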