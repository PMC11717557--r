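#' Simulate a synthetic rs-fMRI quality-control cohort
#'
#' Generates a cohort with the covariate, motion, and connectivity structure
#' the exclusion-bias audit assumes, so every downstream stage can be
#' exercised without access-controlled data. The generative model is:
#'
#' * **Covariates.** A Gaussian copula ties the 17 covariates together through
#'   a single latent "compound disadvantage" factor with configurable
#'   loadings; categorical covariates are cut from their latent scores at the
#'   quantiles of configurable marginal frequencies. The psychopathology
#'   factor scores (p, INT, EXT) have zero loadings and independent latents,
#'   so they are mutually orthogonal by construction.
#' * **Motion.** Each subject has a latent motion propensity
#'   `lambda_i = sum_c effect_c * z_ic + N(0, propensity_sd)` over the
#'   standardized latent covariate scores `z`. Six rigid-body parameter series
#'   per run combine AR(1) baseline noise, a respiratory sinusoid added to the
#'   translations, and transient displacement spikes occurring per frame with
#'   probability `plogis(qlogis(spike_base_rate) + lambda_i)` and
#'   shifted-exponential magnitude.
#' * **Pre-motion QC.** Failure of pre-motion processing is Bernoulli on a
#'   logistic scale with configurable covariate and site effects; independent
#'   low-rate visual-inspection and segmentation failure flags feed the
#'   tabulated and recommended inclusion pathways.
#' * **Connectivity.** ROI time series are latent-network signal plus noise
#'   plus a motion-locked artifact whose contribution to an edge's signal
#'   covariance is `(artifact_base + artifact_strength * mean unfiltered FD)
#'   * exp(-distance / artifact_distance_decay)`, concentrated in high-FD
#'   frames so frame censoring removes it.
#'
#' @param config A [cohort_config()] object.
#' @param components Which blocks to generate: `"covariates"` is always
#'   generated; add `"motion"` for motion traces and `"timeseries"` for ROI
#'   signals (which require motion). Identical config + seed + components give
#'   a bit-identical cohort.
#'
#' @return An object of class `qc_cohort`: a list with elements `subjects`
#'   (data frame of subject records), `latents` (matrix of the standardized
#'   latent covariate scores driving the copula), `propensity` (true motion
#'   propensity, simulation ground truth), `motion` (per-subject list of
#'   per-run `motion_trace` objects), `geometry` (ROI centroid data frame),
#'   `timeseries` (per-subject frames x ROI matrices), and `config`.
#' @export
simulate_cohort <- function(config,
                            components = c("covariates", "motion",
                                           "timeseries")) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  components <- match.arg(components, several.ok = TRUE)
  if ("timeseries" %in% components && !"motion" %in% components)
    stop("'timeseries' requires 'motion' in components", call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(config$seed))

  cohort <- list(config = config)
  cov_block <- simulate_covariates(config)
  cohort$subjects <- cov_block$subjects
  cohort$latents <- cov_block$latents
  cohort$propensity <- cov_block$propensity
  cohort$geometry <- simulate_geometry(config)

  if ("motion" %in% components)
    cohort$motion <- simulate_motion(config, cohort$propensity,
                                     cohort$subjects$subject_id)
  if ("timeseries" %in% components)
    cohort$timeseries <- simulate_timeseries(config, cohort)

  class(cohort) <- "qc_cohort"
  cohort
}

simulate_covariates <- function(config) {
  n <- config$n_subjects
  covs <- analysis_covariates()
  levs <- covariate_levels()
  loadings <- rep(0, length(covs)); names(loadings) <- covs
  loadings[names(config$ses_loadings)] <- config$ses_loadings

  site <- sample.int(config$n_sites, n, replace = TRUE)
  site_score <- if (config$n_sites > 1)
    (site - mean(seq_len(config$n_sites))) / stats::sd(seq_len(config$n_sites))
  else rep(0, n)
  scanner_idx <- sample.int(config$scanners_per_site, n, replace = TRUE)

  u <- stats::rnorm(n)  # shared disadvantage factor
  shift <- rep(0, length(covs)); names(shift) <- covs
  if (!is.null(config$site_covariate_shift))
    shift[names(config$site_covariate_shift)] <- config$site_covariate_shift

  latents <- matrix(NA_real_, n, length(covs), dimnames = list(NULL, covs))
  for (cv in covs) {
    l <- loadings[[cv]]
    latents[, cv] <- l * u + sqrt(1 - l^2) * stats::rnorm(n) +
      shift[[cv]] * site_score
  }

  subjects <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                         stringsAsFactors = FALSE)
  for (cv in covs) {
    if (cv %in% names(levs)) {
      cuts <- c(-Inf, stats::qnorm(cumsum(config$marginals[[cv]])[-length(levs[[cv]])]), Inf)
      subjects[[cv]] <- factor(levs[[cv]][findInterval(latents[, cv], cuts,
                                                       left.open = TRUE) ],
                               levels = levs[[cv]])
    } else {
      subjects[[cv]] <- latents[, cv]
    }
  }
  subjects$site <- factor(sprintf("site%02d", site),
                          levels = sprintf("site%02d", seq_len(config$n_sites)))
  subjects$scanner <- factor(
    sprintf("site%02d_scanner%d", site, scanner_idx),
    levels = as.vector(t(outer(seq_len(config$n_sites),
                               seq_len(config$scanners_per_site),
                               function(s, k) sprintf("site%02d_scanner%d", s, k)))))

  preqc_logit <- stats::qlogis(config$preqc_base_rate)
  for (cv in names(config$preqc_fail_effects))
    preqc_logit <- preqc_logit + config$preqc_fail_effects[[cv]] * latents[, cv]
  if (!is.null(config$site_preqc_logodds))
    preqc_logit <- preqc_logit + config$site_preqc_logodds[site]
  subjects$preqc_fail <- stats::runif(n) < stats::plogis(preqc_logit)
  subjects$visual_fail <- stats::runif(n) < config$visual_fail_rate
  subjects$seg_fail <- stats::runif(n) < config$seg_fail_rate

  propensity <- drop(latents %*% ifelse(covs %in% names(config$covariate_effects),
                                        config$covariate_effects[covs], 0)) +
    stats::rnorm(n, sd = config$propensity_sd)

  list(subjects = subjects, latents = latents, propensity = propensity)
}

simulate_geometry <- function(config) {
  k <- config$n_rois
  # uniform in a 70 mm radius sphere (head-sized coordinate space)
  dir <- matrix(stats::rnorm(3 * k), k, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  r <- 70 * stats::runif(k)^(1 / 3)
  xyz <- dir * r
  data.frame(roi_id = sprintf("roi%03d", seq_len(k)),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

simulate_motion <- function(config, propensity, subject_ids) {
  n <- config$n_subjects
  tf <- config$frames_per_run
  spike_p <- stats::plogis(stats::qlogis(config$spike_base_rate) + propensity)
  noise_sd <- rep(c(config$trans_noise_mm,
                    config$trans_noise_mm / config$head_radius_mm), each = 3)
  param_names <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")

  lapply(seq_len(n), function(i) {
    phase <- stats::runif(2, 0, 2 * pi)
    base_scale <- exp(stats::rnorm(1, sd = config$baseline_scale_sd))
    lapply(seq_len(config$n_runs), function(r) {
      innov <- matrix(stats::rnorm(tf * 6), tf, 6) %*%
        diag(base_scale * noise_sd)
      params <- apply(innov, 2, function(e)
        as.numeric(stats::filter(e, config$ar_phi, method = "recursive")))
      t_global <- ((r - 1) * tf + seq_len(tf)) * config$tr_seconds
      resp <- 2 * pi * config$respiratory_freq_hz * t_global
      params[, 2] <- params[, 2] + config$respiratory_amp_mm * sin(resp + phase[1])
      params[, 3] <- params[, 3] + 0.5 * config$respiratory_amp_mm * sin(resp + phase[2])
      spikes <- which(stats::runif(tf) < spike_p[i])
      if (length(spikes)) {
        mag <- (config$spike_min_mm +
                  stats::rexp(length(spikes), 1 / config$spike_mean_mm)) *
          sample(c(-1, 1), length(spikes), replace = TRUE)
        axis <- sample.int(3, length(spikes), replace = TRUE)
        params[cbind(spikes, axis)] <- params[cbind(spikes, axis)] + mag
      }
      colnames(params) <- param_names
      motion_trace(params, subject_id = subject_ids[i], run_index = r,
                   tr_seconds = config$tr_seconds)
    })
  })
}

simulate_timeseries <- function(config, cohort) {
  k <- config$n_rois
  tt <- config$n_runs * config$frames_per_run
  D <- as.matrix(stats::dist(cohort$geometry[, c("x", "y", "z")]))
  K <- exp(-D / config$artifact_distance_decay)
  L <- t(chol(K + diag(1e-8, k)))
  m <- 6L  # latent networks shared by all subjects
  B <- matrix(stats::rnorm(k * m, sd = config$network_loading), k, m)

  lapply(seq_along(cohort$motion), function(i) {
    fd <- unlist(lapply(cohort$motion[[i]], function(tr)
      compute_fd(tr, config$head_radius_mm)$fd), use.names = FALSE)
    msq <- mean(fd^2)
    w <- if (msq > 0) fd / sqrt(msq) else rep(0, tt)
    amp2 <- config$artifact_base + config$artifact_strength * mean(fd)
    ci <- sqrt(max(0, amp2))
    y <- matrix(stats::rnorm(tt * k), tt, k) +
      matrix(stats::rnorm(tt * m), tt, m) %*% t(B)
    if (ci > 0) {
      f <- matrix(stats::rnorm(tt * k), tt, k) * w
      y <- y + ci * (f %*% t(L))
    }
    colnames(y) <- cohort$geometry$roi_id
    y
  })
}

#' @export
print.qc_cohort <- function(x, ...) {
  cat(sprintf("Synthetic QC cohort: %d subjects", nrow(x$subjects)))
  if (!is.null(x$motion))
    cat(sprintf(", %d run(s) of motion", length(x$motion[[1]])))
  if (!is.null(x$timeseries))
    cat(sprintf(", %d-ROI time series", ncol(x$timeseries[[1]])))
  cat("\n")
  cat(sprintf("  pre-motion QC failures: %d (%.1f%%)\n",
              sum(x$subjects$preqc_fail),
              100 * mean(x$subjects$preqc_fail)))
  invisible(x)
}

#' Construct a rigid-body motion trace
#'
#' @param params Numeric matrix with columns `trans_x`, `trans_y`, `trans_z`
#'   (mm) and `rot_x`, `rot_y`, `rot_z` (radians), one row per frame.
#' @param subject_id,run_index Identifiers.
#' @param tr_seconds Sampling interval in seconds.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(params, subject_id = "sub", run_index = 1L,
                         tr_seconds = 0.8) {
  required <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  params <- as.matrix(params)
  if (!all(required %in% colnames(params)))
    stop("motion trace must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  params <- params[, required, drop = FALSE]
  if (!is.numeric(params))
    stop("motion parameters must be numeric", call. = FALSE)
  structure(list(subject_id = subject_id, run_index = as.integer(run_index),
                 params = params, tr_seconds = tr_seconds),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("Motion trace %s run %d: %d frames @ TR %.3g s\n",
              x$subject_id, x$run_index, nrow(x$params), x$tr_seconds))
  invisible(x)
}
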