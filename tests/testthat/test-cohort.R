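test_that("identical config and seed reproduce the cohort bit for bit", {
  cfg <- cohort_config(n_subjects = 8, seed = 99, n_runs = 2, n_rois = 12,
                       artifact_strength = 1, artifact_base = 0.1)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$motion, b$motion)
  expect_identical(a$geometry, b$geometry)
  expect_identical(a$timeseries, b$timeseries)
  c2 <- simulate_cohort(cohort_config(n_subjects = 8, seed = 100, n_runs = 2,
                                      n_rois = 12))
  expect_false(identical(a$subjects, c2$subjects))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(cohort_config(n_subjects = 0), "n_subjects")
  expect_error(cohort_config(n_subjects = 5, spike_base_rate = 1.2),
               "spike_base_rate")
  expect_error(cohort_config(n_subjects = 5, tr_seconds = -1), "tr_seconds")
  expect_error(cohort_config(n_subjects = 5,
                             covariate_effects = c(nonsense = 1)),
               "nonsense")
  expect_error(cohort_config(n_subjects = 5,
                             site_preqc_logodds = c(0, 1)),
               "site_preqc_logodds")
})

test_that("the cohort has the configured dimensions and all 17 covariates", {
  co <- simulate_cohort(cohort_config(n_subjects = 6, seed = 3, n_runs = 3,
                                      frames_per_run = 50, n_rois = 7))
  expect_equal(nrow(co$subjects), 6)
  expect_true(all(analysis_covariates() %in% names(co$subjects)))
  expect_length(analysis_covariates(), 17)
  expect_length(co$motion, 6)
  expect_length(co$motion[[1]], 3)
  expect_equal(nrow(co$motion[[2]][[1]]$params), 50)
  expect_equal(dim(co$timeseries[[1]]), c(150, 7))
  expect_equal(nrow(co$geometry), 7)
  D <- as.matrix(dist(co$geometry[, c("x", "y", "z")]))
  expect_true(all(D[upper.tri(D)] > 0))
})

test_that("psychopathology factor scores are mutually near-orthogonal", {
  co <- simulate_cohort(cohort_config(n_subjects = 4000, seed = 8),
                        components = "covariates")
  pc <- cor(co$subjects[, c("p_factor", "internalizing", "externalizing")])
  expect_lt(max(abs(pc[upper.tri(pc)])), 0.06)
})

test_that("with all motion effects zero, covariates are uncorrelated with mean FD", {
  co <- quick_cohort(n = 2000, seed = 17,
                     covariate_effects = c(bmi_z = 0),
                     respiratory_amp_mm = 1e-9)
  mfd <- subject_mean_fd(co, filtered = FALSE)
  for (cv in c("bmi_z", "age", "p_factor", "adi"))
    expect_lt(abs(cor(co$subjects[[cv]], mfd)), 0.05)
})

test_that("a positive BMI motion effect produces a positive BMI-FD association", {
  co <- quick_cohort(n = 1000, seed = 23,
                     covariate_effects = c(bmi_z = 0.5),
                     respiratory_amp_mm = 1e-9)
  mfd <- subject_mean_fd(co, filtered = FALSE)
  ct <- cor.test(co$subjects$bmi_z, mfd, method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.001)
})

test_that("larger motion effects give larger FD correlations and exclusion odds", {
  cors <- or_est <- numeric(2)
  for (k in 1:2) {
    eff <- c(0.2, 0.6)[k]
    acc <- c(cor = 0, or = 0)
    for (s in 1:3) {
      co <- quick_cohort(n = 800, seed = 300 + s,
                         covariate_effects = c(bmi_z = eff),
                         respiratory_amp_mm = 1e-9)
      mfd <- subject_mean_fd(co, filtered = FALSE)
      ret <- cohort_retention(co, thresholds = 0.2, filtered = FALSE)
      tab <- data.frame(subject_id = ret$subject_id, "0.2" = ret$excluded,
                        check.names = FALSE)
      or <- fit_bivariate_exclusion(co$subjects, tab, conditions = "0.2",
                                    covariates = "bmi_z")
      acc <- acc + c(cor(co$subjects$bmi_z, mfd), log(or$odds_ratio))
    }
    cors[k] <- acc[1] / 3
    or_est[k] <- acc[2] / 3
  }
  expect_gt(cors[2], cors[1])
  expect_gt(or_est[2], or_est[1])
  expect_gt(or_est[2], 0)
})
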