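#' Compute framewise displacement from rigid-body motion parameters
#'
#' Framewise displacement (FD) is the sum of the absolute backward differences
#' of the six rigid-body realignment parameters, with the three rotations
#' converted to millimetres of arc length on a sphere of radius
#' `head_radius_mm`:
#' `fd[t] = sum_j |delta trans_j[t]| + head_radius * sum_j |delta rot_j[t]|`.
#' The first frame has no predecessor and is assigned `fd[1] = 0`, keeping
#' frame counts aligned with censoring masks.
#'
#' @param trace A [motion_trace()] (translations in mm, rotations in radians).
#' @param head_radius_mm Sphere radius (mm) for the rotational arc length.
#' @return An object of class `fd_series`: list with `subject_id`,
#'   `run_index`, `fd` (nonnegative mm per frame), and `filtered` (whether
#'   respiratory filtering was applied upstream).
#' @export
compute_fd <- function(trace, head_radius_mm = 50) {
  stopifnot(inherits(trace, "motion_trace"))
  if (length(head_radius_mm) != 1L || !is.finite(head_radius_mm) ||
      head_radius_mm <= 0)
    stop("head_radius_mm must be a positive real", call. = FALSE)
  p <- trace$params
  bad <- which(!is.finite(p), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite motion parameter at frame %d (%s)",
                 bad[1, 1], colnames(p)[bad[1, 2]]), call. = FALSE)
  d <- abs(diff(p))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  structure(list(subject_id = trace$subject_id, run_index = trace$run_index,
                 fd = fd, filtered = isTRUE(attr(trace, "filtered"))),
            class = "fd_series")
}

#' Construct an FD series directly
#'
#' Wraps a precomputed framewise displacement vector (e.g. read from file) in
#' the container used by the censoring functions.
#'
#' @param fd Nonnegative numeric vector, `fd[1]` conventionally 0.
#' @param subject_id,run_index Identifiers.
#' @param filtered Whether respiratory filtering was applied upstream.
#' @return An `fd_series` object.
#' @export
fd_series <- function(fd, subject_id = "sub", run_index = 1L,
                      filtered = FALSE) {
  if (any(!is.finite(fd)) || any(fd < 0))
    stop("fd values must be finite and nonnegative", call. = FALSE)
  structure(list(subject_id = subject_id, run_index = as.integer(run_index),
                 fd = as.numeric(fd), filtered = isTRUE(filtered)),
            class = "fd_series")
}

#' Filter respiratory artifact from motion
#'
#' Factitious motion at respiratory frequencies contaminates FD estimates in
#' fast-TR acquisitions. This applies a zero-phase Butterworth band-stop
#' filter (order 2, run forwards and backwards) over the configured stopband,
#' either to each of the six motion parameter series before differencing (the
#' default) or to an FD series directly.
#'
#' @param x A [motion_trace()] or [fd_series()] object. The trace target is
#'   the default behaviour of `censor_config()`; passing an `fd_series`
#'   corresponds to `filter_target = "fd_series"`.
#' @param config A [censor_config()] carrying `respiratory_stopband_hz`.
#' @param tr_seconds Sampling interval; taken from the trace when available.
#' @return An object of the same class as `x`, marked as filtered. Output
#'   length equals input length. Filter warm-up: roughly the first and last
#'   10 frames carry edge transients and should not be interpreted
#'   frequency-wise.
#' @export
filter_respiratory <- function(x, config = censor_config(),
                               tr_seconds = NULL) {
  band <- config$respiratory_stopband_hz
  if (inherits(x, "motion_trace")) {
    tr <- x$tr_seconds
    nyq <- 1 / (2 * tr)
    check_stopband(band, nyq)
    bf <- signal::butter(2, band / nyq, type = "stop")
    p <- x$params
    if (nrow(p) < 24L)
      stop("trace too short for respiratory filtering (need >= 24 frames)",
           call. = FALSE)
    # demean before filtering so the DC level is preserved exactly
    filt <- apply(p, 2, function(col) {
      mu <- mean(col)
      signal::filtfilt(bf, col - mu) + mu
    })
    colnames(filt) <- colnames(p)
    out <- motion_trace(filt, subject_id = x$subject_id,
                        run_index = x$run_index, tr_seconds = tr)
    attr(out, "filtered") <- TRUE
    out
  } else if (inherits(x, "fd_series")) {
    if (is.null(tr_seconds))
      stop("tr_seconds is required when filtering an fd_series", call. = FALSE)
    nyq <- 1 / (2 * tr_seconds)
    check_stopband(band, nyq)
    if (length(x$fd) < 24L)
      stop("fd series too short for respiratory filtering (need >= 24 frames)",
           call. = FALSE)
    bf <- signal::butter(2, band / nyq, type = "stop")
    mu <- mean(x$fd)
    fd <- signal::filtfilt(bf, x$fd - mu) + mu
    structure(list(subject_id = x$subject_id, run_index = x$run_index,
                   fd = pmax(fd, 0), filtered = TRUE),
              class = "fd_series")
  } else {
    stop("x must be a motion_trace or fd_series", call. = FALSE)
  }
}

check_stopband <- function(band, nyquist) {
  if (length(band) != 2L || any(!is.finite(band)) || any(band <= 0) ||
      band[1] >= band[2])
    stop("respiratory stopband must be an increasing pair of positive frequencies",
         call. = FALSE)
  if (band[2] >= nyquist)
    stop(sprintf(
      "respiratory stopband upper edge (%.3g Hz) is at or above Nyquist (%.3g Hz); sampling rate must exceed twice the stopband",
      band[2], nyquist), call. = FALSE)
  invisible(band)
}

#' Per-subject mean framewise displacement
#'
#' Convenience summary used by the bias and QC-FC analyses: mean FD over all
#' frames of all runs (before any censoring), optionally after respiratory
#' filtering of the motion parameters.
#'
#' @param cohort A `qc_cohort` with motion traces.
#' @param filtered Apply the respiratory filter before computing FD.
#' @param config [censor_config()] supplying the stopband and head radius.
#' @return Named numeric vector of mean FD (mm) by subject id.
#' @export
subject_mean_fd <- function(cohort, filtered = TRUE,
                            config = censor_config()) {
  stopifnot(inherits(cohort, "qc_cohort"), !is.null(cohort$motion))
  out <- vapply(cohort$motion, function(runs) {
    mean(unlist(lapply(runs, function(tr) {
      if (filtered) tr <- filter_respiratory(tr, config)
      compute_fd(tr, config$head_radius_mm)$fd
    }), use.names = FALSE))
  }, numeric(1))
  names(out) <- cohort$subjects$subject_id
  out
}
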