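small_audit_config <- function(seed = 61) {
  cohort_config(n_subjects = 60, seed = seed, n_runs = 2, n_rois = 12)
}

test_that("the end-to-end audit is deterministic and writes its artifact set", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  a1 <- qc_audit(small_audit_config(), output_dir = d1)
  a2 <- qc_audit(small_audit_config(), output_dir = d2)

  expected <- c("exclusion_table.csv", "condition_summary.csv",
                "retention.csv", "table2_correlations.csv",
                "table3_contrasts.csv", "table4_bivariate_or.csv",
                "table5_adjusted_or.csv", "fig5_trajectory.csv",
                "qcfc_edges_none.csv", "qcfc_binned_none.csv",
                "qcfc_edges_0.2.csv", "qcfc_binned_0.2.csv",
                "qcfc_summary.json", "run_summary.json")
  expect_true(all(expected %in% list.files(d1)))
  for (f in expected)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_identical(a1$config_hash, a2$config_hash)
  expect_equal(a1$seed, 61L)

  # different seed changes the outputs
  a3 <- qc_audit(small_audit_config(seed = 62))
  expect_false(identical(a1$condition_summary, a3$condition_summary))
})

test_that("the audit object carries consistent components and methods", {
  a <- qc_audit(small_audit_config())
  expect_s3_class(a, "qc_audit")
  expect_equal(nrow(a$exclusion_table), 60)
  expect_equal(sort(unique(a$bivariate_or$condition)),
               sort(qc_condition_ids()))
  # 17 covariates modelled in each condition
  expect_equal(length(unique(a$bivariate_or$covariate)), 17)
  expect_true(all(c("none", "0.2") %in% names(a$qcfc)))
  expect_equal(a$qcfc$none$n_edges +
                 sum(is.na(a$qcfc$none$edges$qcfc_r)), 12 * 11 / 2)
  expect_output(print(a), "exclusion by condition")
  s <- summary(a)
  expect_true(all(s$n_associated <= s$n_terms))
  # odds ratios within their intervals wherever defined
  ok <- a$bivariate_or[a$bivariate_or$flag == "ok", ]
  expect_true(all(ok$ci_low <= ok$odds_ratio & ok$odds_ratio <= ok$ci_high))
})

test_that("run_audit reproduces qc_audit from a config file", {
  d <- withr::local_tempdir()
  f <- file.path(d, "run.yaml")
  rc <- run_config(small_audit_config(), qcfc_scrub = NA,
                   output_dir = file.path(d, "out"))
  write_run_config(rc, f)
  a <- run_audit(f)
  expect_s3_class(a, "qc_audit")
  expect_true(file.exists(file.path(d, "out", "run_summary.json")))
  js <- jsonlite::read_json(file.path(d, "out", "run_summary.json"))
  expect_equal(js$seed, 61L)
  expect_equal(js$config_hash, a$config_hash)
})

test_that("the command-line front end validates inputs and simulates", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "qcaudit.R", package = "scrubbias")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")

  bad <- suppressWarnings(
    system2(rscript, c(cli, "censor", "--threshold", "0",
                       "--input", "nothing.tsv"),
            stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(bad, "status")))

  d <- withr::local_tempdir()
  out <- suppressWarnings(
    system2(rscript, c(cli, "simulate", "--n", "4", "--seed", "3",
                       "--out", shQuote(file.path(d, "cohort"))),
            stdout = TRUE, stderr = TRUE))
  expect_null(attr(out, "status"))
  expect_true(file.exists(file.path(d, "cohort", "manifest.json")))
  expect_length(list.files(file.path(d, "cohort"),
                           pattern = "_motion.tsv$"), 16)
})
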