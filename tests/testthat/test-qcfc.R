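test_that("connectivity of identical signals is 1 and respects the mask contract", {
  set.seed(6)
  s <- rnorm(200)
  ts <- cbind(a = s, b = s, c = rnorm(200))
  r <- compute_connectivity(ts)
  expect_equal(r["a", "b"], 1)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r, t(r))
  expect_true(all(abs(r) <= 1))

  expect_error(compute_connectivity(ts, keep = rep(TRUE, 10)),
               "mask length")
  expect_error(compute_connectivity(ts, keep = c(TRUE, TRUE,
                                                 rep(FALSE, 198))),
               "retained frames")
})

test_that("independent white-noise ROIs have near-zero edges", {
  set.seed(7)
  ts <- matrix(rnorm(1500 * 20), 1500, 20)
  r <- compute_connectivity(ts)
  off <- abs(r[upper.tri(r)])
  expect_gt(mean(off < 0.07), 0.95)
})

test_that("censoring the frames carrying a shared spike removes its correlation", {
  set.seed(8)
  n <- 400
  spike <- rep(0, n); spike[101:110] <- 15
  ts <- cbind(a = rnorm(n) + spike, b = rnorm(n) + spike)
  keep <- rep(TRUE, n); keep[101:110] <- FALSE
  r_all <- compute_connectivity(ts)["a", "b"]
  r_masked <- compute_connectivity(ts, keep)["a", "b"]
  expect_gt(r_all, 0.7)
  expect_lt(r_masked, r_all - 0.5)
  expect_lt(abs(r_masked), 0.15)
})

test_that("zero-variance ROIs are flagged and their edges undefined", {
  ts <- cbind(a = rnorm(100), b = rep(1, 100), c = rnorm(100))
  r <- compute_connectivity(ts)
  expect_equal(attr(r, "flagged_rois"), "b")
  expect_true(is.na(r["a", "b"]))
  expect_false(is.na(r["a", "c"]))
})

test_that("Fisher z mode transforms and clips", {
  s <- rnorm(100)
  ts <- cbind(a = s, b = s, c = s + rnorm(100, sd = 0.5))
  z <- compute_connectivity(ts, fisher_z = TRUE)
  expect_equal(z["a", "b"], atanh(1 - 1e-7))
  r <- compute_connectivity(ts)
  expect_equal(z["a", "c"], atanh(r["a", "c"]))
})

test_that("QC-FC recovers a constructed motion-connectivity dependence", {
  set.seed(9)
  n <- 60; k <- 3
  geom <- data.frame(roi_id = c("r1", "r2", "r3"),
                     x = c(0, 10, 50), y = 0, z = 0)
  fd <- runif(n, 0.05, 0.4)
  mats <- lapply(seq_len(n), function(i) {
    m <- diag(k); dimnames(m) <- list(geom$roi_id, geom$roi_id)
    m[1, 2] <- m[2, 1] <- 0.9 * fd[i] + rnorm(1, sd = 1e-4)
    m[1, 3] <- m[3, 1] <- 0.1
    m[2, 3] <- m[3, 2] <- rnorm(1, sd = 0.05)
    m
  })
  edges <- compute_qcfc(mats, fd, geom)
  expect_equal(nrow(edges), k * (k - 1) / 2)
  e12 <- edges[edges$roi_a == "r1" & edges$roi_b == "r2", ]
  expect_gt(e12$qcfc_r, 0.99)
  expect_equal(e12$distance_mm, 10)
  e13 <- edges[edges$roi_a == "r1" & edges$roi_b == "r3", ]
  expect_true(is.na(e13$qcfc_r))
  expect_equal(e13$flag, "zero_variance")

  expect_error(compute_qcfc(mats, rep(0.2, n), geom), "constant")
  expect_error(compute_qcfc(mats[1:2], fd[1:2], geom), "3 subjects")
})

test_that("a flat QC-FC field has exactly zero slope; edge count is complete", {
  set.seed(10)
  k <- 8
  geom <- data.frame(roi_id = sprintf("r%d", 1:k),
                     x = runif(k, -50, 50), y = runif(k, -50, 50),
                     z = runif(k, -50, 50))
  edges <- data.frame(roi_a = "a", roi_b = "b",
                      distance_mm = as.matrix(dist(geom[, 2:4]))[upper.tri(diag(k))],
                      qcfc_r = 0.07, n_subjects = 50, flag = "ok")
  expect_equal(nrow(edges), k * (k - 1) / 2)
  s <- qcfc_distance_summary(edges)
  expect_identical(s$slope, 0)
  expect_identical(c(s$ci_low, s$ci_high), c(0, 0))
  expect_equal(s$intercept, 0.07)
  expect_equal(sum(s$binned_medians$n_edges), nrow(edges))
})

test_that("null and artifact simulations behave as constructed", {
  # no artifact: QC-FC centred on zero, slope interval covers zero
  cfg0 <- cohort_config(n_subjects = 80, seed = 55, n_runs = 1, n_rois = 20,
                        respiratory_amp_mm = 1e-9, artifact_strength = 0)
  co0 <- simulate_cohort(cfg0)
  mfd0 <- subject_mean_fd(co0, filtered = FALSE)
  mats0 <- lapply(co0$timeseries, compute_connectivity, fisher_z = TRUE)
  s0 <- qcfc_distance_summary(compute_qcfc(mats0, mfd0, co0$geometry))
  expect_lt(mean(abs(s0$edges$qcfc_r)), 0.15)
  expect_true(s0$ci_low <= 0 && s0$ci_high >= 0)

  # short-range artifact scaling with motion: negative distance slope,
  # attenuated by scrubbing at 0.2 mm
  cfg1 <- cohort_config(n_subjects = 120, seed = 56, n_runs = 1, n_rois = 30,
                        respiratory_amp_mm = 1e-9, artifact_strength = 2)
  co1 <- simulate_cohort(cfg1)
  mfd1 <- subject_mean_fd(co1, filtered = FALSE)
  cc <- censor_config(threshold_mm = 0.2)
  masks <- lapply(co1$motion, function(runs)
    concat_masks(lapply(runs, function(tr)
      build_censor_mask(compute_fd(tr), cc))))
  usable <- vapply(masks, sum, numeric(1)) >= 10
  m_un <- lapply(which(usable), function(i)
    compute_connectivity(co1$timeseries[[i]], fisher_z = TRUE))
  m_sc <- lapply(which(usable), function(i)
    compute_connectivity(co1$timeseries[[i]], masks[[i]], fisher_z = TRUE))
  s_un <- qcfc_distance_summary(compute_qcfc(m_un, mfd1[usable], co1$geometry))
  s_sc <- qcfc_distance_summary(compute_qcfc(m_sc, mfd1[usable], co1$geometry))
  expect_lt(s_un$ci_high, 0)
  expect_lt(abs(s_sc$slope), abs(s_un$slope))
})
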