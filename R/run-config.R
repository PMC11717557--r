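#' Serializable audit run configuration
#'
#' Bundles the cohort, censoring, and analysis settings of an audit run into
#' a structure that round-trips through a YAML file, so runs are fully
#' reproducible from a config plus a seed.
#'
#' @param cohort A [cohort_config()], or a path to a directory written by
#'   [write_cohort()].
#' @param censor A [censor_config()].
#' @param thresholds Motion thresholds (mm).
#' @param ci_level,qcfc_ci_level Confidence levels for odds ratios and the
#'   QC-FC slope.
#' @param include_site,include_scanner Site/scanner controls for the
#'   adjusted models.
#' @param qcfc_scrub QC-FC scrubbing levels (`NA` = no censoring).
#' @param fisher_z Use Fisher z connectivity for QC-FC.
#' @param output_dir Output directory for [qc_audit()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort, censor = censor_config(),
                       thresholds = c(0.5, 0.4, 0.3, 0.2, 0.1),
                       ci_level = 0.90, qcfc_ci_level = 0.99,
                       include_site = FALSE, include_scanner = FALSE,
                       qcfc_scrub = c(NA, 0.2), fisher_z = TRUE,
                       output_dir = "audit_out") {
  if (!inherits(cohort, "cohort_config") && !is.character(cohort))
    stop("cohort must be a cohort_config or an input directory path",
         call. = FALSE)
  structure(list(cohort = cohort, censor = censor, thresholds = thresholds,
                 ci_level = ci_level, qcfc_ci_level = qcfc_ci_level,
                 include_site = include_site,
                 include_scanner = include_scanner,
                 qcfc_scrub = qcfc_scrub, fisher_z = fisher_z,
                 output_dir = output_dir),
            class = "run_config")
}

#' Read and write run configurations
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config()` returns a `run_config` equal (over all
#'   settings) to the one written.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  if (inherits(x$cohort, "cohort_config")) {
    x$cohort <- unclass(x$cohort)
    x$cohort_kind <- "config"
    # named numeric vectors -> named lists for faithful YAML round-trip
    for (f in c("covariate_effects", "preqc_fail_effects", "ses_loadings",
                "site_covariate_shift"))
      if (!is.null(x$cohort[[f]]))
        x$cohort[[f]] <- as.list(x$cohort[[f]])
  } else {
    x$cohort_kind <- "path"
  }
  x$censor <- unclass(x$censor)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  if (identical(x$cohort_kind, "config")) {
    cc <- x$cohort
    for (f in c("covariate_effects", "preqc_fail_effects", "ses_loadings",
                "site_covariate_shift"))
      if (!is.null(cc[[f]])) cc[[f]] <- unlist(cc[[f]])
    cc$marginals <- lapply(cc$marginals, as.numeric)
    cohort <- do.call(cohort_config, cc)
  } else {
    cohort <- x$cohort
  }
  cs <- x$censor
  censor <- censor_config(threshold_mm = cs$threshold_mm,
                          min_island = cs$min_island,
                          min_retained_frames = cs$min_retained_frames,
                          head_radius_mm = cs$head_radius_mm,
                          respiratory_stopband_hz = as.numeric(cs$respiratory_stopband_hz),
                          filter_target = cs$filter_target,
                          censor_boundary_islands = cs$censor_boundary_islands)
  run_config(cohort = cohort, censor = censor,
             thresholds = as.numeric(x$thresholds),
             ci_level = x$ci_level, qcfc_ci_level = x$qcfc_ci_level,
             include_site = x$include_site,
             include_scanner = x$include_scanner,
             qcfc_scrub = as.numeric(x$qcfc_scrub),
             fisher_z = x$fisher_z, output_dir = x$output_dir)
}

#' Run an audit from a run configuration
#'
#' @param config A [run_config()] or path to a YAML config file.
#' @param seed Optional integer overriding the cohort seed.
#' @return The `qc_audit` object (outputs are written to
#'   `config$output_dir`).
#' @export
run_audit <- function(config, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cohort <- config$cohort
  if (inherits(cohort, "cohort_config")) {
    if (!is.null(seed)) cohort$seed <- as.integer(seed)
    cohort <- simulate_cohort(cohort)
  } else {
    cohort <- read_cohort(cohort)
  }
  qc_audit(cohort, censor = config$censor, thresholds = config$thresholds,
           ci_level = config$ci_level, qcfc_ci_level = config$qcfc_ci_level,
           include_site = config$include_site,
           include_scanner = config$include_scanner,
           qcfc_scrub = config$qcfc_scrub, fisher_z = config$fisher_z,
           output_dir = config$output_dir)
}
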