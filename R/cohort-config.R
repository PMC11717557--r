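#' The 17 analysis covariates
#'
#' Names of the demographic, cognitive, psychopathology, and health covariates
#' carried by every simulated subject record and entered into the exclusion
#' bias models. Six are categorical (sex, household income, parent education,
#' race/ethnicity, trauma count, pubertal status) and eleven are continuous
#' standardized scores.
#'
#' @return Character vector of length 17.
#' @export
analysis_covariates <- function() {
  c("sex", "income_level", "parent_education", "race_ethnicity",
    "trauma_count", "puberty",
    "adi", "coi",
    "nihtb_flanker", "nihtb_crystallized", "nihtb_total", "wisc_matrix",
    "p_factor", "internalizing", "externalizing",
    "age", "bmi_z")
}

#' @rdname analysis_covariates
#' @export
continuous_covariates <- function() {
  c("adi", "coi", "nihtb_flanker", "nihtb_crystallized", "nihtb_total",
    "wisc_matrix", "p_factor", "internalizing", "externalizing",
    "age", "bmi_z")
}

#' @rdname analysis_covariates
#' @export
categorical_covariates <- function() {
  c("sex", "income_level", "parent_education", "race_ethnicity",
    "trauma_count", "puberty")
}

# Factor levels for the categorical covariates; first element is NOT the
# reference -- reference levels follow the study's model parameterization and
# are recorded in covariate_reference_levels().
covariate_levels <- function() {
  list(
    sex              = c("F", "M"),
    income_level     = c("$0-25k", "$25-50k", "$50-75k", "$75-100k",
                         "$100-200k", "$200k+"),
    parent_education = c("<HS", "HS", "some_college", "college", "graduate"),
    race_ethnicity   = c("White", "Black", "Hispanic", "Asian", "Other"),
    trauma_count     = c("0", "1", "2+"),
    puberty          = c("pre", "early", "mid", "late", "post")
  )
}

covariate_reference_levels <- function() {
  c(sex = "F", income_level = "$100-200k", parent_education = "college",
    race_ethnicity = "White", trauma_count = "0", puberty = "pre")
}

# Default marginal category frequencies for the simulator (large pediatric
# multi-site cohort orders of magnitude; not estimates of any real sample).
default_marginals <- function() {
  list(
    sex              = c(0.50, 0.50),
    income_level     = c(0.10, 0.13, 0.13, 0.14, 0.30, 0.20),
    parent_education = c(0.05, 0.10, 0.26, 0.26, 0.33),
    race_ethnicity   = c(0.52, 0.15, 0.20, 0.02, 0.11),
    trauma_count     = c(0.55, 0.25, 0.20),
    puberty          = c(0.50, 0.30, 0.15, 0.04, 0.01)
  )
}

# Single-factor "compound disadvantage" loadings for the Gaussian copula that
# ties covariates together. Sign convention: positive loading = higher latent
# disadvantage. The psychopathology factor scores (p, INT, EXT) load zero so
# they are mutually orthogonal by construction; sex is independent of the
# disadvantage factor.
default_ses_loadings <- function() {
  c(sex = 0, income_level = -0.65, parent_education = -0.60,
    race_ethnicity = 0.45, trauma_count = 0.30, puberty = 0.05,
    adi = 0.70, coi = -0.70,
    nihtb_flanker = -0.30, nihtb_crystallized = -0.45, nihtb_total = -0.50,
    wisc_matrix = -0.35,
    p_factor = 0, internalizing = 0, externalizing = 0,
    age = 0, bmi_z = 0.25)
}

# Default log-scale effects of each covariate's standardized latent score on
# the motion spike propensity. Signs mirror the direction of the
# FD-covariate associations the audit is designed to surface (heavier, male,
# younger, more disadvantaged, higher general psychopathology -> more motion).
default_covariate_effects <- function() {
  c(sex = 0.20, income_level = -0.18, parent_education = -0.16,
    race_ethnicity = 0.18, trauma_count = 0.08, puberty = 0,
    adi = 0.10, coi = -0.14,
    nihtb_flanker = -0.06, nihtb_crystallized = -0.10, nihtb_total = -0.16,
    wisc_matrix = -0.10,
    p_factor = 0.10, internalizing = -0.04, externalizing = 0,
    age = -0.14, bmi_z = 0.35)
}

# Log-odds effects on failing pre-motion QC (the community-collection
# pre-processing pathway).
default_preqc_effects <- function() {
  c(income_level = -0.20, parent_education = -0.18, race_ethnicity = 0.22,
    coi = -0.12, adi = 0.06, nihtb_total = -0.12, age = -0.10, bmi_z = 0.04)
}

#' Configure a synthetic rs-fMRI quality-control cohort
#'
#' Builds the configuration object consumed by [simulate_cohort()]. Defaults
#' emulate a large pediatric multi-site resting-state study: four 5-minute
#' runs at TR = 0.8 s (375 frames each), a latent motion propensity that is a
#' linear function of the standardized covariate scores, framewise
#' displacement traces combining autocorrelated baseline noise, a respiratory
#' sinusoid, and covariate-graded high-motion spikes, and ROI time series
#' carrying an optional distance-dependent motion artifact.
#'
#' @param n_subjects Number of subjects.
#' @param n_runs Resting-state runs per subject.
#' @param frames_per_run Frames per run.
#' @param tr_seconds Repetition time (sampling interval) in seconds.
#' @param n_rois Number of regions of interest for connectivity.
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   cohort.
#' @param covariate_effects Named numeric: effect of each covariate's
#'   standardized latent score on the log-odds motion spike propensity.
#' @param propensity_sd SD of the subject-level propensity noise term.
#' @param spike_base_rate Per-frame probability of a high-motion spike for a
#'   subject at propensity 0; must lie in (0, 1).
#' @param spike_min_mm,spike_mean_mm Shifted-exponential spike displacement:
#'   minimum and mean of the exponential excess (mm), so spikes exceed all
#'   scrubbing thresholds at graded rates.
#' @param trans_noise_mm Innovation SD of the AR(1) baseline noise on each
#'   translation parameter (rotations use `trans_noise_mm / head_radius`).
#' @param baseline_scale_sd SD (log scale) of the per-subject multiplier on
#'   the baseline noise level, capturing covariate-independent variation in
#'   continuous motion between subjects.
#' @param ar_phi AR(1) coefficient of the baseline parameter noise.
#' @param head_radius_mm Head radius used to scale rotational noise.
#' @param respiratory_freq_hz Frequency of the factitious respiratory
#'   oscillation added to the translations.
#' @param respiratory_amp_mm Amplitude (mm) of the respiratory oscillation.
#' @param artifact_strength Scale (delta) of the motion-induced connectivity
#'   artifact: the artifact contribution to an edge's signal covariance is
#'   `(artifact_base + delta * mean unfiltered FD) * exp(-distance / decay)`.
#'   Negative values (with a positive `artifact_base`) make high-motion
#'   subjects lose short-range coupling instead of gaining it.
#' @param artifact_base Motion-independent part of the artifact covariance.
#' @param artifact_distance_decay Length scale (mm) of the artifact's
#'   distance dependence.
#' @param network_loading SD of the shared latent network signal giving all
#'   subjects a common baseline connectivity structure.
#' @param preqc_base_rate Baseline probability of failing pre-motion QC.
#' @param preqc_fail_effects Named numeric log-odds effects of covariate
#'   latent scores on pre-motion QC failure.
#' @param visual_fail_rate Baseline rate of the tabulated-release visual
#'   inspection failure flag (an independent low-rate pathway).
#' @param seg_fail_rate Baseline rate of the segmentation failure flag used
#'   by the recommended-inclusion condition.
#' @param n_sites Number of collection sites.
#' @param scanners_per_site Scanner models per site.
#' @param site_preqc_logodds Optional numeric vector (length `n_sites`) of
#'   site intercept shifts on the pre-motion QC failure log-odds.
#' @param site_covariate_shift Named numeric: shift of a covariate's latent
#'   mean per unit standardized site score (creates site-covariate
#'   confounding).
#' @param ses_loadings Named numeric copula loadings on the shared
#'   disadvantage factor.
#' @param marginals Named list of categorical marginal frequencies.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [simulate_cohort()], [write_cohort()]
#' @export
cohort_config <- function(n_subjects,
                          n_runs = 4L,
                          frames_per_run = 375L,
                          tr_seconds = 0.8,
                          n_rois = 60L,
                          seed = 1L,
                          covariate_effects = default_covariate_effects(),
                          propensity_sd = 2.0,
                          spike_base_rate = 0.025,
                          spike_min_mm = 0.12,
                          spike_mean_mm = 0.18,
                          trans_noise_mm = 0.016,
                          baseline_scale_sd = 0.4,
                          ar_phi = 0.3,
                          head_radius_mm = 50,
                          respiratory_freq_hz = 0.35,
                          respiratory_amp_mm = 0.05,
                          artifact_strength = 0,
                          artifact_base = 0,
                          artifact_distance_decay = 50,
                          network_loading = 0.4,
                          preqc_base_rate = 0.19,
                          preqc_fail_effects = default_preqc_effects(),
                          visual_fail_rate = 0.043,
                          seg_fail_rate = 0.07,
                          n_sites = 8L,
                          scanners_per_site = 2L,
                          site_preqc_logodds = NULL,
                          site_covariate_shift = NULL,
                          ses_loadings = default_ses_loadings(),
                          marginals = default_marginals()) {
  cfg <- list(
    n_subjects = n_subjects, n_runs = n_runs, frames_per_run = frames_per_run,
    tr_seconds = tr_seconds, n_rois = n_rois, seed = seed,
    covariate_effects = covariate_effects, propensity_sd = propensity_sd,
    spike_base_rate = spike_base_rate, spike_min_mm = spike_min_mm,
    spike_mean_mm = spike_mean_mm, trans_noise_mm = trans_noise_mm,
    baseline_scale_sd = baseline_scale_sd,
    ar_phi = ar_phi, head_radius_mm = head_radius_mm,
    respiratory_freq_hz = respiratory_freq_hz,
    respiratory_amp_mm = respiratory_amp_mm,
    artifact_strength = artifact_strength, artifact_base = artifact_base,
    artifact_distance_decay = artifact_distance_decay,
    network_loading = network_loading,
    preqc_base_rate = preqc_base_rate,
    preqc_fail_effects = preqc_fail_effects,
    visual_fail_rate = visual_fail_rate, seg_fail_rate = seg_fail_rate,
    n_sites = n_sites, scanners_per_site = scanners_per_site,
    site_preqc_logodds = site_preqc_logodds,
    site_covariate_shift = site_covariate_shift,
    ses_loadings = ses_loadings, marginals = marginals
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  chk_count <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != floor(v))
      stop(sprintf("invalid cohort config: '%s' must be a positive count", field),
           call. = FALSE)
  }
  chk_pos <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("invalid cohort config: '%s' must be a positive real", field),
           call. = FALSE)
  }
  chk_rate <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1L || !is.finite(v) || v <= 0 || v >= 1)
      stop(sprintf("invalid cohort config: '%s' must lie in (0, 1)", field),
           call. = FALSE)
  }
  chk_nonneg <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("invalid cohort config: '%s' must be nonnegative", field),
           call. = FALSE)
  }
  for (f in c("n_subjects", "n_runs", "frames_per_run", "n_rois", "n_sites",
              "scanners_per_site"))
    chk_count(f)
  for (f in c("tr_seconds", "head_radius_mm", "respiratory_freq_hz",
              "artifact_distance_decay", "spike_min_mm", "spike_mean_mm",
              "trans_noise_mm"))
    chk_pos(f)
  for (f in c("spike_base_rate", "preqc_base_rate"))
    chk_rate(f)
  for (f in c("respiratory_amp_mm", "propensity_sd", "artifact_base",
              "network_loading", "baseline_scale_sd"))
    chk_nonneg(f)
  if (length(cfg$seed) != 1L || !is.finite(cfg$seed) ||
      cfg$seed != floor(cfg$seed))
    stop("invalid cohort config: 'seed' must be an integer", call. = FALSE)
  if (abs(cfg$ar_phi) >= 1)
    stop("invalid cohort config: 'ar_phi' must lie in (-1, 1)", call. = FALSE)
  for (f in c("covariate_effects", "preqc_fail_effects", "ses_loadings",
              "site_covariate_shift")) {
    v <- cfg[[f]]
    if (is.null(v)) next
    if (length(v) && (is.null(names(v)) || any(!nzchar(names(v)))))
      stop(sprintf("invalid cohort config: '%s' must be a named numeric vector", f),
           call. = FALSE)
    bad <- setdiff(names(v), analysis_covariates())
    if (length(bad))
      stop(sprintf("invalid cohort config: '%s' names unknown covariate(s): %s",
                   f, paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(cfg$site_preqc_logodds) &&
      length(cfg$site_preqc_logodds) != cfg$n_sites)
    stop("invalid cohort config: 'site_preqc_logodds' must have length n_sites",
         call. = FALSE)
  if (any(abs(cfg$ses_loadings) > 0.95))
    stop("invalid cohort config: 'ses_loadings' entries must lie in [-0.95, 0.95]",
         call. = FALSE)
  for (m in names(default_marginals())) {
    p <- cfg$marginals[[m]]
    if (is.null(p) || length(p) != length(covariate_levels()[[m]]) ||
        any(p <= 0) || abs(sum(p) - 1) > 1e-8)
      stop(sprintf("invalid cohort config: 'marginals$%s' must be positive frequencies summing to 1", m),
           call. = FALSE)
  }
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic rs-fMRI QC cohort configuration\n")
  cat(sprintf("  subjects: %d   runs: %d x %d frames (TR %.3g s)\n",
              x$n_subjects, x$n_runs, x$frames_per_run, x$tr_seconds))
  cat(sprintf("  ROIs: %d   sites: %d   seed: %d\n",
              x$n_rois, x$n_sites, as.integer(x$seed)))
  eff <- x$covariate_effects[x$covariate_effects != 0]
  cat(sprintf("  motion effects on %d covariate(s); spike base rate %.3g; propensity sd %.3g\n",
              length(eff), x$spike_base_rate, x$propensity_sd))
  cat(sprintf("  respiratory %.2f Hz @ %.3g mm; artifact delta %.3g (decay %.3g mm)\n",
              x$respiratory_freq_hz, x$respiratory_amp_mm,
              x$artifact_strength, x$artifact_distance_decay))
  invisible(x)
}
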