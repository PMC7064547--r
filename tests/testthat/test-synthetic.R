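# Synthetic-cohort generator: shapes, determinism, marginal fidelity,
# and the latent-trait links.

test_that("default cohort has the study dimensions", {
  coh <- generate_cohort(cohort_config(seed = 1))
  expect_equal(nrow(coh$trials), 74 * (5 + 20 + 5))
  expect_equal(nrow(coh$clinical), 74)
  expect_equal(nrow(coh$truth), 74 * 3)
  expect_true(all(coh$clinical$dgi_total %in% 0:24))
  expect_true(all(coh$clinical$moca_total %in% 21:30))
  expect_true(all(coh$trials$outcome %in% 0:1))
  expect_true(all(coh$trials$response_time_s >= 0))
  expect_true(all(table(coh$trials$patient_id) == 30))
  expect_setequal(coh$trials$patient_id, coh$clinical$patient_id)
  expect_true(all(coh$truth$gamma_true > 1 / 3 & coh$truth$gamma_true <= 1))
})

test_that("identical config and seed reproduce the cohort byte for byte", {
  a <- generate_cohort(cohort_config(n_patients = 20, seed = 99))
  b <- generate_cohort(cohort_config(n_patients = 20, seed = 99))
  expect_identical(a$trials, b$trials)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(cohort_config(n_patients = 20, seed = 100))
  expect_false(identical(a$trials$outcome, c2$trials$outcome))
})

test_that("population marginals match the configured values at n = 5000", {
  cfg <- cohort_config(n_patients = 5000, seed = 12)
  coh <- generate_cohort(cfg)
  for (s in 1:3) {
    tr <- coh$truth[coh$truth$stage == s, ]
    # 2 Monte-Carlo standard errors of the mean (sd known from config)
    expect_lt(abs(mean(tr$beta_true) - cfg$beta_mean[s]),
              2 * cfg$beta_sd[s] / sqrt(5000) + 0.01)
    expect_lt(abs(sd(tr$beta_true) - cfg$beta_sd[s]), 0.05)
    expect_lt(abs(mean(tr$gamma_true) - cfg$gamma_mean[s]),
              2 * cfg$gamma_sd[s] / sqrt(5000) + 0.005)
    expect_lt(abs(sd(tr$gamma_true) - cfg$gamma_sd[s]), 0.02)
    expect_lt(abs(mean(tr$tbar_true) - cfg$time_mean[s]),
              3 * cfg$time_sd[s] / sqrt(5000) + 0.05)
  }
})

test_that("latent links carry the calibrated correlations and vanish at zero", {
  cfg <- cohort_config(n_patients = 8000, seed = 5)
  coh <- generate_cohort(cfg)
  g3 <- coh$truth$gamma_true[coh$truth$stage == 3]
  ps <- polyserial_correlation(g3, coh$clinical$dgi_total)
  expect_lt(abs(ps$estimate - 0.39), 0.04)
  pc <- polychoric_correlation(coh$clinical$moca_total,
                               coh$clinical$dgi_total)
  expect_lt(abs(pc$estimate - 0.20), 0.04)

  null_cfg <- cohort_config(n_patients = 8000, link_scale = 0,
                            moca_link = 0, seed = 5)
  nco <- generate_cohort(null_cfg)
  g3n <- nco$truth$gamma_true[nco$truth$stage == 3]
  expect_lt(abs(polyserial_correlation(
    g3n, nco$clinical$dgi_total)$estimate), 0.04)
})

test_that("link calibration honors trivial and infeasible targets", {
  cfg <- calibrate_link(c(gamma3 = 0), cohort_config(), n = 2000, seed = 3)
  expect_identical(cfg$link_scale, 0)
  expect_error(
    calibrate_link(c(gamma3 = 0.995), cohort_config(), n = 2000, seed = 3),
    "unattainable")
  expect_error(calibrate_link(c(gamma3 = 1.2), cohort_config()))
})

test_that("cohort files round-trip through the CSV dialects", {
  coh <- generate_cohort(cohort_config(n_patients = 10, seed = 8))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.txt")))
  tr <- read_trials(file.path(dir, "trials.csv"))
  cl <- read_clinical(file.path(dir, "clinical.csv"))
  expect_equal(tr, coh$trials)
  expect_equal(cl$dgi_total, coh$clinical$dgi_total)
  manifest <- readLines(file.path(dir, "manifest.txt"))
  expect_true(any(grepl("^seed: 8$", manifest)))
  expect_true(any(grepl("^config_hash: ", manifest)))
})
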