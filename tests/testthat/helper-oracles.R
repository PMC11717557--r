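# Independent brute-force oracle for the censoring rule: scan the
# post-threshold mask for maximal runs of kept frames and censor every run of
# length <= min_island that is flanked by censored frames (boundary runs
# count as flanked under the boundary convention). Deliberately written as a
# frame-by-frame scan, independent of the rle-based implementation.
oracle_censor <- function(fd, threshold, min_island = 5L,
                          censor_boundary = TRUE) {
  keep <- fd <= threshold
  n <- length(keep)
  out <- keep
  i <- 1L
  while (i <= n) {
    if (!keep[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && keep[j + 1L]) j <- j + 1L
    run_len <- j - i + 1L
    flanked_left <- i > 1L
    flanked_right <- j < n
    flanked <- (flanked_left || censor_boundary) &&
      (flanked_right || censor_boundary)
    if (run_len <= min_island && flanked) out[i:j] <- FALSE
    i <- j + 1L
  }
  out
}

# constant-parameter motion trace with optional single-parameter steps
toy_trace <- function(n_frames, steps = list(), tr = 0.8) {
  p <- matrix(0, n_frames, 6,
              dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                      "rot_x", "rot_y", "rot_z")))
  for (s in steps) p[s$from:n_frames, s$param] <- p[s$from:n_frames, s$param] + s$delta
  motion_trace(p, tr_seconds = tr)
}

quick_cohort <- function(n = 100, seed = 1, runs = 1L, rois = 10L, ...) {
  simulate_cohort(cohort_config(n_subjects = n, seed = seed, n_runs = runs,
                                n_rois = rois, ...),
                  components = c("covariates", "motion"))
}
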