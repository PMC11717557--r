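default_trajectory_groups <- function(records) {
  gs <- list(trajectory_group("race_ethnicity", level = "Black"),
             trajectory_group("income_level", level = "$0-25k"),
             trajectory_group("parent_education", level = "<HS"),
             trajectory_group("bmi_z", cut = 1.5, direction = "above"),
             trajectory_group("p_factor", cut = 1.5, direction = "above"),
             trajectory_group("nihtb_total", cut = 1.5, direction = "below"))
  keep <- vapply(gs, function(g) {
    v <- records[[g$covariate]]
    !is.null(v)
  }, logical(1))
  gs[keep]
}

#' Hash a configuration object
#'
#' Stable MD5 digest of an R object's deparsed form, recorded in audit
#' outputs so runs can be matched to their configuration.
#'
#' @param x Any R object.
#' @return Character MD5 string.
#' @export
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(x, control = c("exact")), tf)
  unname(tools::md5sum(tf))
}

#' Run the full exclusion-bias audit
#'
#' End-to-end pipeline: framewise displacement with respiratory filtering,
#' censor masks and retained-frame accounting at each motion threshold,
#' assembly of the eight inclusion conditions, FD-covariate correlations and
#' contrasts, bivariate and adjusted exclusion odds-ratio models with
#' Bonferroni families, the excess-missingness trajectory, and (when ROI
#' time series are present) QC-FC distance-dependence summaries with and
#' without scrubbing.
#'
#' @param cohort A `qc_cohort` (from [simulate_cohort()] or [read_cohort()])
#'   or a [cohort_config()], which is simulated first.
#' @param censor Base [censor_config()].
#' @param thresholds Motion thresholds (mm) defining the scrubbing
#'   conditions.
#' @param ci_level Confidence level for odds-ratio intervals.
#' @param qcfc_ci_level Confidence level for the QC-FC distance slope.
#' @param families Bonferroni families for the exclusion models.
#' @param groups Trajectory group specifications
#'   ([trajectory_group()]); defaults to a standard set of high-risk
#'   subgroups.
#' @param include_site Control for collection site in the adjusted models.
#' @param include_scanner Control for scanner in the adjusted models.
#' @param qcfc Compute QC-FC diagnostics (requires time series).
#' @param qcfc_scrub Scrubbing levels for QC-FC: numeric thresholds, with
#'   `NA` meaning no censoring.
#' @param fisher_z Enter connectivity as Fisher z in the QC-FC correlation.
#' @param output_dir Optional directory; when given, all table analogs are
#'   written as CSV plus a JSON run summary.
#' @return An object of class `qc_audit` with elements `exclusion_table`,
#'   `condition_summary`, `retention`, `mean_fd`, `fd_correlations`,
#'   `fd_contrasts`, `bivariate_or`, `adjusted_or`, `trajectory`, `qcfc`
#'   (named list of `qcfc_summary` by scrub level), `seed`, and
#'   `config_hash`.
#' @export
qc_audit <- function(cohort,
                     censor = censor_config(),
                     thresholds = c(0.5, 0.4, 0.3, 0.2, 0.1),
                     ci_level = 0.90,
                     qcfc_ci_level = 0.99,
                     families = default_bonferroni_families(),
                     groups = NULL,
                     include_site = FALSE,
                     include_scanner = FALSE,
                     qcfc = NULL,
                     qcfc_scrub = c(NA, 0.2),
                     fisher_z = TRUE,
                     output_dir = NULL) {
  if (inherits(cohort, "cohort_config"))
    cohort <- simulate_cohort(cohort)
  stopifnot(inherits(cohort, "qc_cohort"))
  if (is.null(cohort$motion))
    stop("the audit needs motion traces", call. = FALSE)
  if (is.null(qcfc)) qcfc <- !is.null(cohort$timeseries)

  retention <- cohort_retention(cohort, thresholds, censor)
  table <- assemble_conditions(cohort$subjects, retention,
                               thresholds = thresholds,
                               min_retained_frames = censor$min_retained_frames)
  mean_fd <- subject_mean_fd(cohort, filtered = TRUE, censor)

  thr_conds <- as.character(thresholds)
  fd_cor <- correlate_fd_continuous(cohort$subjects, mean_fd, table,
                                    conditions = thr_conds)
  fd_con <- contrast_fd_categorical(cohort$subjects, mean_fd, table,
                                    conditions = thr_conds)
  conds <- intersect(qc_condition_ids(), names(table))
  biv <- apply_bonferroni(
    fit_bivariate_exclusion(cohort$subjects, table, conditions = conds,
                            ci_level = ci_level), families)
  adj <- apply_bonferroni(
    fit_adjusted_exclusion(cohort$subjects, table, conditions = conds,
                           ci_level = ci_level, include_site = include_site,
                           include_scanner = include_scanner), families)
  if (is.null(groups)) groups <- default_trajectory_groups(cohort$subjects)
  traj <- excess_missingness_trajectory(cohort$subjects, table, groups,
                                        conditions = conds)

  qcfc_res <- NULL
  if (qcfc) {
    if (is.null(cohort$timeseries))
      stop("QC-FC requested but the cohort has no ROI time series",
           call. = FALSE)
    qcfc_res <- list()
    for (scrub in qcfc_scrub) {
      if (is.na(scrub)) {
        masks <- NULL
        label <- "none"
      } else {
        cfg <- censor
        cfg$threshold_mm <- scrub
        masks <- lapply(cohort$motion, function(runs)
          concat_masks(lapply(runs, function(tr) {
            ftr <- filter_respiratory(tr, cfg)
            build_censor_mask(compute_fd(ftr, cfg$head_radius_mm), cfg)
          })))
        label <- as.character(scrub)
      }
      mats <- vector("list", length(cohort$timeseries))
      usable <- rep(TRUE, length(mats))
      for (i in seq_along(mats)) {
        keep <- if (is.null(masks)) NULL else masks[[i]]
        nk <- if (is.null(keep)) nrow(cohort$timeseries[[i]]) else sum(keep)
        if (nk < 3L) { usable[i] <- FALSE; next }
        mats[[i]] <- compute_connectivity(cohort$timeseries[[i]], keep,
                                          fisher_z = fisher_z)
      }
      edges <- compute_qcfc(mats[usable], mean_fd[usable], cohort$geometry)
      qcfc_res[[label]] <- qcfc_distance_summary(edges,
                                                 ci_level = qcfc_ci_level)
    }
  }

  res <- structure(list(
    exclusion_table = table,
    condition_summary = condition_summary(table),
    retention = retention,
    mean_fd = mean_fd,
    fd_correlations = fd_cor,
    fd_contrasts = fd_con,
    bivariate_or = biv,
    adjusted_or = adj,
    trajectory = traj,
    qcfc = qcfc_res,
    seed = if (!is.null(cohort$config$seed)) as.integer(cohort$config$seed) else NA_integer_,
    config_hash = config_hash(cohort$config)
  ), class = "qc_audit")
  if (!is.null(output_dir)) write_audit(res, output_dir)
  res
}

#' Write audit outputs
#'
#' Writes the table analogs produced by [qc_audit()] as CSV files
#' (`exclusion_table.csv`, `condition_summary.csv`,
#' `table2_correlations.csv`, `table3_contrasts.csv`,
#' `table4_bivariate_or.csv`, `table5_adjusted_or.csv`,
#' `fig5_trajectory.csv`, `qcfc_edges_<scrub>.csv`, `qcfc_binned_<scrub>.csv`)
#' plus `run_summary.json` recording the seed, configuration hash, package
#' version, and per-condition exclusion percentages (one decimal).
#'
#' @param audit A `qc_audit` object.
#' @param output_dir Output directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_audit <- function(audit, output_dir) {
  stopifnot(inherits(audit, "qc_audit"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, fn) utils::write.csv(df, file.path(output_dir, fn),
                                         row.names = FALSE)
  tab <- audit$exclusion_table
  out_tab <- data.frame(subject_id = tab$subject_id)
  for (cn in setdiff(names(tab), "subject_id"))
    out_tab[[cn]] <- as.integer(tab[[cn]])
  w(out_tab, "exclusion_table.csv")
  w(audit$condition_summary, "condition_summary.csv")
  w(audit$retention, "retention.csv")
  w(audit$fd_correlations, "table2_correlations.csv")
  w(audit$fd_contrasts, "table3_contrasts.csv")
  w(audit$bivariate_or, "table4_bivariate_or.csv")
  w(audit$adjusted_or, "table5_adjusted_or.csv")
  w(audit$trajectory, "fig5_trajectory.csv")
  qcfc_json <- NULL
  if (!is.null(audit$qcfc)) {
    qcfc_json <- lapply(audit$qcfc, function(s)
      list(slope = s$slope, ci_low = s$ci_low, ci_high = s$ci_high,
           ci_level = s$ci_level, intercept = s$intercept,
           n_edges = s$n_edges))
    for (label in names(audit$qcfc)) {
      s <- audit$qcfc[[label]]
      w(s$edges, sprintf("qcfc_edges_%s.csv", label))
      w(s$binned_medians, sprintf("qcfc_binned_%s.csv", label))
    }
    jsonlite::write_json(qcfc_json, file.path(output_dir, "qcfc_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  cs <- audit$condition_summary
  jsonlite::write_json(
    list(seed = audit$seed, config_hash = audit$config_hash,
         package_version = as.character(utils::packageVersion("scrubbias")),
         r_version = R.version.string,
         pct_excluded = stats::setNames(as.list(round(cs$pct_excluded, 1)),
                                        cs$condition)),
    file.path(output_dir, "run_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.qc_audit <- function(x, ...) {
  cat("rs-fMRI QC exclusion-bias audit\n")
  cat(sprintf("  %d subjects, seed %s, config %s\n",
              nrow(x$exclusion_table), x$seed,
              substr(x$config_hash, 1, 8)))
  s <- x$condition_summary
  cat("  exclusion by condition:\n")
  cat(paste(sprintf("    %-4s %5d (%.1f%%)", s$condition, s$n_excluded,
                    s$pct_excluded), collapse = "\n"), "\n")
  sig <- x$bivariate_or[x$bivariate_or$flag == "ok" &
                          x$bivariate_or$p_corrected < 1 - x$bivariate_or$ci_level, ]
  cat(sprintf("  bivariate models: %d of %d terms associated with exclusion (alpha = %.2f)\n",
              nrow(sig), nrow(x$bivariate_or),
              1 - x$bivariate_or$ci_level[1]))
  if (!is.null(x$qcfc)) {
    for (label in names(x$qcfc)) {
      s <- x$qcfc[[label]]
      cat(sprintf("  QC-FC distance slope (scrub %s): %.2e [%.2e, %.2e] (%d%% CI)\n",
                  label, s$slope, s$ci_low, s$ci_high,
                  round(100 * s$ci_level)))
    }
  }
  invisible(x)
}

#' @export
summary.qc_audit <- function(object, ...) {
  or <- object$bivariate_or
  ok <- or[or$flag == "ok" & or$term != "(Intercept)", ]
  alpha <- 1 - ok$ci_level[1]
  data.frame(
    condition = unique(ok$condition),
    n_terms = as.integer(table(ok$condition)[unique(ok$condition)]),
    n_associated = vapply(unique(ok$condition), function(cn)
      sum(ok$p_corrected[ok$condition == cn] < alpha), numeric(1)),
    row.names = NULL)
}

#' @export
plot.qc_audit <- function(x, which = c("trajectory", "qcfc"), ...) {
  which <- match.arg(which)
  if (which == "trajectory") {
    tr <- x$trajectory
    groups <- unique(tr$group)
    cols <- grDevices::hcl.colors(max(3, length(groups)), "Dark 3")
    graphics::plot(NULL, xlim = range(tr$pct_data_excluded),
                   ylim = range(tr$excess),
                   xlab = "% of data excluded",
                   ylab = "excess missingness (pp)", ...)
    graphics::abline(h = 0, lty = 3)
    for (i in seq_along(groups)) {
      g <- tr[tr$group == groups[i], ]
      g <- g[order(g$pct_data_excluded), ]
      graphics::lines(g$pct_data_excluded, g$excess, col = cols[i], lwd = 2)
      graphics::points(g$pct_data_excluded, g$excess, col = cols[i], pch = 16)
    }
    graphics::legend("topleft", legend = groups, col = cols[seq_along(groups)],
                     lwd = 2, bty = "n", cex = 0.8)
  } else {
    if (is.null(x$qcfc)) stop("no QC-FC results in this audit", call. = FALSE)
    plot(x$qcfc[[1]], ...)
  }
  invisible(x)
}
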