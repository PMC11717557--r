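fake_records <- function(n, ...) {
  cbind(data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                   stringsAsFactors = FALSE),
        data.frame(..., stringsAsFactors = FALSE))
}

test_that("a covariate equal to mean FD correlates perfectly; degenerate input is flagged", {
  set.seed(1)
  fd <- setNames(runif(50, 0.05, 0.3), sprintf("S%04d", 1:50))
  rec <- fake_records(50, x = unname(fd), const = 1)
  res <- correlate_fd_continuous(rec, fd, conditions = "0.2",
                                 covariates = "x", sample = "all")
  expect_equal(res$estimate, 1)
  expect_lt(res$p_value, 1e-10)

  res0 <- correlate_fd_continuous(rec, fd, conditions = "0.2",
                                  covariates = "const", sample = "all")
  expect_true(is.na(res0$estimate))
  expect_equal(res0$flag, "zero_variance")
})

test_that("independent covariates show near-zero FD correlation", {
  set.seed(2)
  fd <- setNames(runif(2000, 0.05, 0.3), sprintf("S%04d", 1:2000))
  rec <- fake_records(2000, x = rnorm(2000))
  res <- correlate_fd_continuous(rec, fd, conditions = "0.2",
                                 covariates = "x", sample = "all")
  expect_lt(abs(res$estimate), 0.05)
})

test_that("a one-SD group shift recovers the closed-form standardized contrast", {
  # y_B = y_A + delta with within-group sd s: standardized beta =
  # delta / sqrt(s^2 + delta^2/4) for balanced groups
  set.seed(3)
  n <- 4000
  g <- rep(c("F", "M"), each = n / 2)
  y <- rnorm(n) + (g == "M") * 1
  rec <- fake_records(n, sex = g)
  fd <- setNames(y, rec$subject_id)
  res <- contrast_fd_categorical(rec, fd, conditions = "0.2",
                                 covariates = "sex", sample = "all")
  expect_equal(res$estimate, 1 / sqrt(1 + 0.25), tolerance = 0.05)
  expect_match(res$contrast_label, "M — F")
  expect_lt(res$omnibus_p, 1e-10)

  rec1 <- fake_records(10, sex = rep("F", 10))
  expect_error(contrast_fd_categorical(rec1, setNames(rnorm(10), rec1$subject_id),
                                       conditions = "0.2", covariates = "sex",
                                       sample = "all"),
               "single level")
})

test_that("identical group distributions give null contrasts", {
  set.seed(4)
  ps <- replicate(60, {
    n <- 200
    y <- rnorm(n)
    rec <- fake_records(n, sex = sample(rep(c("F", "M"), each = n / 2)))
    res <- contrast_fd_categorical(rec, setNames(y, rec$subject_id),
                                   conditions = "0.2", covariates = "sex",
                                   sample = "all")
    res$omnibus_p
  })
  expect_gt(mean(ps), 0.35)  # roughly uniform p-values
  expect_lt(mean(ps), 0.65)
  expect_gt(min(ps), 1e-5)
})

test_that("the intercept-only exclusion model returns the exclusion odds", {
  tab <- data.frame(subject_id = sprintf("S%04d", 1:100),
                    C = rep(c(TRUE, FALSE), c(25, 75)))
  rec <- fake_records(100, age = rnorm(100))
  res <- fit_bivariate_exclusion(rec, tab, conditions = "C",
                                 covariates = character(0))
  expect_equal(res$odds_ratio, 1 / 3, tolerance = 1e-6)
})

test_that("Wald p-values and intervals agree about excluding the null", {
  co <- simulate_cohort(cohort_config(n_subjects = 600, seed = 12),
                        components = "covariates")
  tab <- data.frame(subject_id = co$subjects$subject_id,
                    C = co$subjects$preqc_fail)
  res <- fit_bivariate_exclusion(co$subjects, tab, conditions = "C")
  ok <- res[res$flag == "ok", ]
  excl <- ok$ci_low > 1 | ok$ci_high < 1
  expect_identical(excl, ok$p_value < 0.10)
})

test_that("complete separation is flagged, not silently estimated", {
  tab <- data.frame(subject_id = sprintf("S%04d", 1:40),
                    C = rep(c(TRUE, FALSE), each = 20))
  rec <- fake_records(40, x = rep(c(5, -5), each = 20))
  res <- suppressWarnings(
    fit_bivariate_exclusion(rec, tab, conditions = "C", covariates = "x"))
  expect_equal(res$flag, "separation")
  expect_true(is.na(res$odds_ratio))

  tab1 <- data.frame(subject_id = rec$subject_id, C = rep(TRUE, 40))
  expect_error(fit_bivariate_exclusion(rec, tab1, conditions = "C",
                                       covariates = "x"),
               "single outcome class")
})

test_that("profile intervals are available and bracket the Wald estimate", {
  co <- simulate_cohort(cohort_config(n_subjects = 500, seed = 19),
                        components = "covariates")
  tab <- data.frame(subject_id = co$subjects$subject_id,
                    C = co$subjects$preqc_fail)
  wald <- fit_bivariate_exclusion(co$subjects, tab, conditions = "C",
                                  covariates = "bmi_z")
  prof <- fit_bivariate_exclusion(co$subjects, tab, conditions = "C",
                                  covariates = "bmi_z", method = "profile")
  expect_equal(prof$odds_ratio, wald$odds_ratio)
  expect_equal(prof$ci_low, wald$ci_low, tolerance = 0.05)
  expect_true(prof$ci_low < prof$odds_ratio &
                prof$odds_ratio < prof$ci_high)
})

test_that("adjustment attenuates the odds ratio of a correlated non-causal covariate", {
  # pre-motion failure depends only on ADI; COI is strongly negatively
  # correlated with ADI through the shared disadvantage factor
  cfg <- cohort_config(n_subjects = 4000, seed = 31,
                       preqc_fail_effects = c(adi = 0.7))
  co <- simulate_cohort(cfg, components = "covariates")
  tab <- data.frame(subject_id = co$subjects$subject_id,
                    C = co$subjects$preqc_fail)
  biv <- fit_bivariate_exclusion(co$subjects, tab, conditions = "C",
                                 covariates = c("adi", "coi"))
  adj <- fit_adjusted_exclusion(co$subjects, tab, conditions = "C",
                                covariates = c("adi", "coi"))
  or_biv <- biv$odds_ratio[biv$covariate == "coi"]
  or_adj <- adj$odds_ratio[adj$covariate == "coi"]
  expect_lt(or_biv, 0.9)                      # confounded association
  expect_lt(abs(log(or_adj)), abs(log(or_biv)))  # attenuated toward 1
})

test_that("rank-deficient adjusted designs are rejected with the aliased terms", {
  co <- simulate_cohort(cohort_config(n_subjects = 200, seed = 41),
                        components = "covariates")
  rec <- co$subjects
  rec$adi_copy <- rec$adi
  tab <- data.frame(subject_id = rec$subject_id, C = rec$preqc_fail)
  expect_error(fit_adjusted_exclusion(rec, tab, conditions = "C",
                                      covariates = c("adi", "adi_copy")),
               "aliased.*adi_copy")
})

test_that("Bonferroni families multiply and cap p-values, leaving others alone", {
  res <- data.frame(covariate = c("adi", "coi", "wisc_matrix", "bmi_z"),
                    p_value = c(0.03, 0.5, 0.4, 0.04))
  fam <- list(neighborhood = c("adi", "coi"),
              cognition = "wisc_matrix")
  out <- apply_bonferroni(res, fam)
  expect_equal(out$p_corrected, c(0.06, 1.0, 0.4, 0.04))
  expect_equal(out$corrected_family,
               c("neighborhood", "neighborhood", "cognition", NA))

  out3 <- apply_bonferroni(data.frame(covariate = "wisc_matrix",
                                      p_value = 0.5),
                           list(cog = c("wisc_matrix")))
  expect_equal(out3$p_corrected, 0.5)
  expect_error(apply_bonferroni(res, list(a = "adi", b = "adi")),
               "at most one family")
  expect_error(apply_bonferroni(res, list(a = "unknown_cov")),
               "unknown covariate")
})

test_that("excess missingness is simple arithmetic with exact endpoints", {
  rec <- fake_records(100, grp = rep(c("A", "B"), c(30, 70)))
  # group A: 9/30 = 30% excluded; overall 20/100 = 20%
  tab <- data.frame(subject_id = rec$subject_id,
                    mid = c(rep(TRUE, 9), rep(FALSE, 21),
                            rep(TRUE, 11), rep(FALSE, 59)),
                    none = FALSE, all = TRUE)
  tr <- excess_missingness_trajectory(rec, tab,
                                      list(trajectory_group("grp", level = "A")),
                                      conditions = c("none", "mid", "all"))
  expect_equal(tr$excess[tr$condition == "mid"], 10.0)
  expect_identical(tr$excess[tr$condition == "none"], 0)
  expect_identical(tr$excess[tr$condition == "all"], 0)
  expect_equal(tr$pct_data_excluded, sort(tr$pct_data_excluded))

  expect_warning(
    empty <- excess_missingness_trajectory(
      rec, tab, list(trajectory_group("grp", level = "Z")),
      conditions = "mid"),
    "empty")
  expect_null(empty)
})

test_that("continuous group cuts select the intended tails", {
  rec <- fake_records(1000, score = rnorm(1000))
  tab <- data.frame(subject_id = rec$subject_id,
                    cond = rec$score > 1)  # exclusion concentrated in high tail
  tr_hi <- excess_missingness_trajectory(
    rec, tab, list(trajectory_group("score", cut = 1.5, direction = "above")),
    conditions = "cond")
  tr_lo <- excess_missingness_trajectory(
    rec, tab, list(trajectory_group("score", cut = 1.5, direction = "below")),
    conditions = "cond")
  expect_gt(tr_hi$excess, 50)
  expect_lt(tr_lo$excess, 0)
})

test_that("covariate missingness is tallied per covariate", {
  co <- simulate_cohort(cohort_config(n_subjects = 50, seed = 2),
                        components = "covariates")
  rec <- co$subjects
  rec$coi[1:5] <- NA
  mis <- covariate_missingness(rec)
  expect_equal(mis$n_missing[mis$covariate == "coi"], 5)
  expect_equal(mis$pct_missing[mis$covariate == "coi"], 10)
  expect_equal(sum(mis$n_missing), 5)
})
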