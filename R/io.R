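motion_columns <- function() c("trans_x", "trans_y", "trans_z",
                               "rot_x", "rot_y", "rot_z")

read_table_checked <- function(path, sep, required, numeric_cols,
                               allow_extra = FALSE, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  if (!nrow(df)) stop("no data rows in ", path, call. = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s in %s", what,
                 paste(missing, collapse = ", "), path), call. = FALSE)
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    if (!allow_extra)
      stop(sprintf("%s: unexpected column(s) %s in %s", what,
                   paste(extra, collapse = ", "), path), call. = FALSE)
    warning(sprintf("%s: extra column(s) %s in %s preserved", what,
                    paste(extra, collapse = ", "), path), call. = FALSE)
  }
  for (cn in intersect(numeric_cols, names(df))) {
    v <- df[[cn]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad))
        stop(sprintf("%s: non-numeric value '%s' at %s line %d, column %s",
                     what, v[bad[1]], path, bad[1] + 1L, cn), call. = FALSE)
      v <- conv
    }
    if (anyNA(v) && cn %in% required) {
      bad <- which(is.na(v))
      stop(sprintf("%s: missing numeric value at %s line %d, column %s", what,
                   path, bad[1] + 1L, cn), call. = FALSE)
    }
    df[[cn]] <- v
  }
  df
}

#' Read and write motion parameter tables
#'
#' Motion files are confounds-style TSVs with the exact (case-sensitive)
#' header `trans_x, trans_y, trans_z, rot_x, rot_y, rot_z` (mm, mm, mm, rad,
#' rad, rad), one row per frame.
#'
#' @param path File path.
#' @param subject_id,run_index,tr_seconds Metadata attached to the returned
#'   trace.
#' @return `read_motion_tsv()` returns a [motion_trace()];
#'   `write_motion_tsv()` returns `path` invisibly.
#' @export
read_motion_tsv <- function(path, subject_id = NULL, run_index = NULL,
                            tr_seconds = 0.8) {
  if (is.null(subject_id) || is.null(run_index)) {
    m <- regmatches(basename(path),
                    regexec("sub-([^_]+)_run-([0-9]+)", basename(path)))[[1]]
    if (length(m) == 3) {
      if (is.null(subject_id)) subject_id <- m[2]
      if (is.null(run_index)) run_index <- as.integer(m[3])
    } else {
      if (is.null(subject_id)) subject_id <- basename(path)
      if (is.null(run_index)) run_index <- 1L
    }
  }
  df <- read_table_checked(path, "\t", motion_columns(), motion_columns(),
                           what = "motion table")
  motion_trace(as.matrix(df[, motion_columns()]), subject_id = subject_id,
               run_index = run_index, tr_seconds = tr_seconds)
}

#' @rdname read_motion_tsv
#' @param trace A [motion_trace()] to write.
#' @export
write_motion_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "motion_trace"))
  df <- as.data.frame(trace$params)
  ok <- try(utils::write.table(format(df, digits = 17, trim = TRUE,
                                      scientific = FALSE),
                               path, sep = "\t", quote = FALSE,
                               row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write motion table: ", path, call. = FALSE)
  invisible(path)
}

#' Read and write subject covariate tables
#'
#' Covariate files are CSVs with one row per subject and column names exactly
#' as the subject record fields. Unknown extra columns are accepted with a
#' warning and preserved.
#'
#' @param path File path.
#' @return `read_covariates_csv()` returns a subject record data frame with
#'   categorical covariates as factors at the study levels.
#' @export
read_covariates_csv <- function(path) {
  required <- c("subject_id", analysis_covariates(), "site", "scanner",
                "preqc_fail", "visual_fail", "seg_fail")
  df <- read_table_checked(path, ",", required, continuous_covariates(),
                           allow_extra = TRUE, what = "covariates table")
  levs <- covariate_levels()
  for (cv in names(levs)) {
    bad <- setdiff(unique(df[[cv]][!is.na(df[[cv]])]), levs[[cv]])
    if (length(bad))
      stop(sprintf("covariates table: unknown level(s) %s for %s in %s",
                   paste(bad, collapse = ", "), cv, path), call. = FALSE)
    df[[cv]] <- factor(df[[cv]], levels = levs[[cv]])
  }
  df$site <- factor(df$site)
  df$scanner <- factor(df$scanner)
  for (fl in c("preqc_fail", "visual_fail", "seg_fail"))
    df[[fl]] <- as.logical(df[[fl]])
  df
}

#' @rdname read_covariates_csv
#' @param records Subject record data frame to write.
#' @export
write_covariates_csv <- function(records, path) {
  ok <- try(utils::write.csv(records, path, row.names = FALSE,
                             quote = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write covariates table: ", path, call. = FALSE)
  invisible(path)
}

#' Read and write ROI centroid tables
#'
#' Centroid files are TSVs with header `roi_id, x, y, z` (mm).
#'
#' @param path File path.
#' @return `read_centroids_tsv()` returns the geometry data frame.
#' @export
read_centroids_tsv <- function(path) {
  df <- read_table_checked(path, "\t", c("roi_id", "x", "y", "z"),
                           c("x", "y", "z"), what = "centroid table")
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("centroid table: non-finite coordinate in ", path, call. = FALSE)
  df$roi_id <- as.character(df$roi_id)
  df
}

#' @rdname read_centroids_tsv
#' @param geometry Geometry data frame to write.
#' @export
write_centroids_tsv <- function(geometry, path) {
  ok <- try(utils::write.table(format(geometry, digits = 17, trim = TRUE,
                                      scientific = FALSE),
                               path, sep = "\t", quote = FALSE,
                               row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write centroid table: ", path, call. = FALSE)
  invisible(path)
}

#' Read and write ROI time-series tables
#'
#' Time-series files are TSVs of frames x ROIs with the ROI ids as header,
#' frame-aligned with the subject's concatenated motion traces.
#'
#' @param path File path.
#' @return `read_timeseries_tsv()` returns a numeric matrix with ROI column
#'   names.
#' @export
read_timeseries_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m))
    stop("time-series table: non-numeric values in ", path, call. = FALSE)
  m
}

#' @rdname read_timeseries_tsv
#' @param ts Frames x ROIs matrix to write.
#' @export
write_timeseries_tsv <- function(ts, path) {
  ok <- try(utils::write.table(format(as.data.frame(ts), digits = 17,
                                      trim = TRUE, scientific = FALSE),
                               path, sep = "\t", quote = FALSE,
                               row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write time-series table: ", path, call. = FALSE)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Writes the covariate CSV, per-subject per-run motion TSVs
#' (`sub-<id>_run-<k>_motion.tsv`), the ROI centroid TSV, per-subject
#' time-series TSVs (when present), and a JSON manifest listing every file
#' together with the generating seed. All numeric content round-trips
#' through the matching readers to within 1e-12.
#'
#' @param cohort A `qc_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly: list with `seed`, `tr_seconds`, `files`.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "qc_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(covariates = "covariates.csv", centroids = "roi_centroids.tsv",
                motion = character(0), timeseries = character(0))
  write_covariates_csv(cohort$subjects, file.path(out_dir, files$covariates))
  write_centroids_tsv(cohort$geometry, file.path(out_dir, files$centroids))
  if (!is.null(cohort$motion)) {
    for (i in seq_along(cohort$motion)) {
      sid <- cohort$subjects$subject_id[i]
      for (tr in cohort$motion[[i]]) {
        fn <- sprintf("sub-%s_run-%d_motion.tsv", sid, tr$run_index)
        write_motion_tsv(tr, file.path(out_dir, fn))
        files$motion <- c(files$motion, fn)
      }
    }
  }
  if (!is.null(cohort$timeseries)) {
    for (i in seq_along(cohort$timeseries)) {
      sid <- cohort$subjects$subject_id[i]
      fn <- sprintf("sub-%s_timeseries.tsv", sid)
      write_timeseries_tsv(cohort$timeseries[[i]], file.path(out_dir, fn))
      files$timeseries <- c(files$timeseries, fn)
    }
  }
  manifest <- list(seed = as.integer(cohort$config$seed),
                   tr_seconds = cohort$config$tr_seconds,
                   n_subjects = nrow(cohort$subjects),
                   n_runs = cohort$config$n_runs, files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.json`.
#' @return A `qc_cohort` (without a simulation config; `seed` and
#'   `tr_seconds` are taken from the manifest).
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir, call. = FALSE)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  subjects <- read_covariates_csv(file.path(dir, mf$files$covariates))
  geometry <- read_centroids_tsv(file.path(dir, mf$files$centroids))
  motion <- NULL
  if (length(mf$files$motion)) {
    motion <- lapply(subjects$subject_id, function(sid) {
      fns <- grep(sprintf("sub-%s_run-", sid), mf$files$motion,
                  value = TRUE, fixed = TRUE)
      lapply(sort(fns), function(fn)
        read_motion_tsv(file.path(dir, fn), tr_seconds = mf$tr_seconds))
    })
  }
  timeseries <- NULL
  if (length(mf$files$timeseries)) {
    timeseries <- lapply(subjects$subject_id, function(sid)
      read_timeseries_tsv(file.path(dir,
                                    sprintf("sub-%s_timeseries.tsv", sid))))
  }
  structure(list(subjects = subjects, geometry = geometry, motion = motion,
                 timeseries = timeseries,
                 manifest = mf,
                 config = list(seed = mf$seed, tr_seconds = mf$tr_seconds,
                               n_runs = mf$n_runs)),
            class = "qc_cohort")
}
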