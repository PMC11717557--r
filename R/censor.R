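#' Configure frame censoring and inclusion rules
#'
#' Bundles the parameters of the scrubbing pipeline: the FD threshold, the
#' contiguous-segment ("island") rule, the minimum retained-data inclusion
#' rule, and the respiratory filter settings.
#'
#' @param threshold_mm FD censoring threshold in mm. The study conditions use
#'   0.5, 0.4, 0.3, 0.2 and 0.1 mm; any positive value is accepted.
#' @param min_island Maximal length of a surviving run of kept frames that is
#'   still censored when flanked by censored frames (default 5: intervals of
#'   no more than five contiguous non-censored frames between two high-motion
#'   frames are removed).
#' @param min_retained_frames Minimum total retained frames across runs for a
#'   subject to be included (default 375 frames = 5 minutes at TR 0.8 s; see
#'   [min_frames_for_minutes()]).
#' @param head_radius_mm Rotational arc-length radius for FD.
#' @param respiratory_stopband_hz Band-stop edges (Hz) of the respiratory
#'   filter.
#' @param filter_target Whether the respiratory filter acts on the six motion
#'   parameters before differencing (default) or on the FD series itself.
#' @param censor_boundary_islands Treat short kept runs at the start or end
#'   of a run as flanked (and censor them when `<= min_island`). This is the
#'   conservative convention; set `FALSE` to keep boundary islands.
#' @return An object of class `censor_config`.
#' @export
censor_config <- function(threshold_mm = 0.2,
                          min_island = 5L,
                          min_retained_frames = 375L,
                          head_radius_mm = 50,
                          respiratory_stopband_hz = c(0.31, 0.43),
                          filter_target = c("motion_parameters", "fd_series"),
                          censor_boundary_islands = TRUE) {
  filter_target <- match.arg(filter_target)
  if (length(threshold_mm) != 1L || !is.finite(threshold_mm) ||
      threshold_mm <= 0)
    stop("threshold_mm must be a positive real", call. = FALSE)
  if (length(min_island) != 1L || min_island < 0 ||
      min_island != floor(min_island))
    stop("min_island must be a nonnegative count", call. = FALSE)
  if (length(min_retained_frames) != 1L || min_retained_frames < 1 ||
      min_retained_frames != floor(min_retained_frames))
    stop("min_retained_frames must be a positive count", call. = FALSE)
  if (length(head_radius_mm) != 1L || head_radius_mm <= 0)
    stop("head_radius_mm must be a positive real", call. = FALSE)
  if (length(respiratory_stopband_hz) != 2L ||
      any(respiratory_stopband_hz <= 0) ||
      respiratory_stopband_hz[1] >= respiratory_stopband_hz[2])
    stop("respiratory_stopband_hz must be an increasing positive pair",
         call. = FALSE)
  structure(list(threshold_mm = threshold_mm,
                 min_island = as.integer(min_island),
                 min_retained_frames = as.integer(min_retained_frames),
                 head_radius_mm = head_radius_mm,
                 respiratory_stopband_hz = respiratory_stopband_hz,
                 filter_target = filter_target,
                 censor_boundary_islands = isTRUE(censor_boundary_islands)),
            class = "censor_config")
}

#' Minimum frame count for a retained-data rule
#'
#' Number of frames required to retain a given number of minutes of data at a
#' given repetition time. Five minutes at TR = 0.8 s gives the canonical 375
#' frame inclusion minimum.
#'
#' @param minutes Minimum retained data in minutes.
#' @param tr_seconds Repetition time in seconds.
#' @return Integer frame count, `ceiling(minutes * 60 / tr_seconds)`.
#' @export
min_frames_for_minutes <- function(minutes = 5, tr_seconds = 0.8) {
  if (minutes <= 0 || tr_seconds <= 0)
    stop("minutes and tr_seconds must be positive", call. = FALSE)
  as.integer(ceiling(minutes * 60 / tr_seconds))
}

#' Build a frame censoring mask from an FD series
#'
#' Two passes: (1) censor every frame whose FD strictly exceeds the threshold
#' (a frame with FD exactly equal to the threshold is kept); (2) censor every
#' maximal run of still-kept frames of length `<= min_island` that is flanked
#' by censored frames — runs touching the start or end of the series are
#' treated as flanked when `censor_boundary_islands` is set (the default).
#'
#' @param fd An [fd_series()].
#' @param config A [censor_config()].
#' @return An object of class `censor_mask`: list with `subject_id`,
#'   `run_index`, `keep` (logical per frame), `n_retained`, and
#'   `threshold_mm`.
#' @export
build_censor_mask <- function(fd, config = censor_config()) {
  stopifnot(inherits(fd, "fd_series"))
  x <- fd$fd
  if (any(!is.finite(x)))
    stop("fd values must be finite", call. = FALSE)
  keep <- x <= config$threshold_mm
  if (config$min_island > 0 && any(!keep)) {
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nruns <- length(r$lengths)
    for (j in seq_len(nruns)) {
      if (!r$values[j] || r$lengths[j] > config$min_island) next
      at_boundary <- j == 1L || j == nruns
      if (!at_boundary || config$censor_boundary_islands)
        keep[starts[j]:ends[j]] <- FALSE
    }
  }
  structure(list(subject_id = fd$subject_id, run_index = fd$run_index,
                 keep = keep, n_retained = sum(keep),
                 threshold_mm = config$threshold_mm),
            class = "censor_mask")
}

#' @export
print.censor_mask <- function(x, ...) {
  cat(sprintf("Censor mask %s run %d @ %.3g mm: %d/%d frames retained\n",
              x$subject_id, x$run_index, x$threshold_mm, x$n_retained,
              length(x$keep)))
  invisible(x)
}

#' Apply the minimum-retained-frames inclusion rule
#'
#' A subject is excluded in a motion condition when fewer than
#' `min_retained_frames` frames survive scrubbing across all runs (strictly
#' fewer: a subject retaining exactly the minimum is included).
#'
#' @param masks List of [build_censor_mask()] results covering all of one
#'   subject's runs at a single threshold.
#' @param config A [censor_config()].
#' @return `TRUE` if the subject is excluded under this condition.
#' @export
flag_motion_exclusion <- function(masks, config = censor_config()) {
  if (inherits(masks, "censor_mask")) masks <- list(masks)
  thr <- vapply(masks, function(m) m$threshold_mm, numeric(1))
  if (length(unique(thr)) != 1L)
    stop("masks mix censoring thresholds: ",
         paste(unique(thr), collapse = ", "), call. = FALSE)
  sum(vapply(masks, function(m) m$n_retained, numeric(1))) <
    config$min_retained_frames
}

#' Retained-frame accounting across a cohort
#'
#' Runs the full scrubbing chain (optional respiratory filtering, FD,
#' censoring) for every subject at each threshold and tallies retained
#' frames.
#'
#' @param cohort A `qc_cohort` with motion traces.
#' @param thresholds FD thresholds (mm) to evaluate.
#' @param config Base [censor_config()]; its threshold is replaced by each
#'   value of `thresholds` in turn.
#' @param filtered Apply respiratory filtering before FD (default TRUE).
#' @return Data frame with columns `subject_id`, `threshold_mm`,
#'   `n_retained`, `excluded`.
#' @export
cohort_retention <- function(cohort, thresholds = c(0.5, 0.4, 0.3, 0.2, 0.1),
                             config = censor_config(), filtered = TRUE) {
  stopifnot(inherits(cohort, "qc_cohort"), !is.null(cohort$motion))
  fd_runs <- lapply(cohort$motion, function(runs)
    lapply(runs, function(tr) {
      if (filtered) {
        if (config$filter_target == "motion_parameters") {
          tr <- filter_respiratory(tr, config)
          compute_fd(tr, config$head_radius_mm)
        } else {
          filter_respiratory(compute_fd(tr, config$head_radius_mm), config,
                             tr_seconds = tr$tr_seconds)
        }
      } else compute_fd(tr, config$head_radius_mm)
    }))
  out <- lapply(thresholds, function(th) {
    cfg <- config
    cfg$threshold_mm <- th
    n_ret <- vapply(fd_runs, function(runs)
      sum(vapply(runs, function(f) build_censor_mask(f, cfg)$n_retained,
                 numeric(1))), numeric(1))
    data.frame(subject_id = cohort$subjects$subject_id,
               threshold_mm = th, n_retained = n_ret,
               excluded = n_ret < cfg$min_retained_frames,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
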