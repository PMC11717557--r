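#' Functional connectivity under frame censoring
#'
#' Pairwise Pearson correlation between ROI time series over retained frames
#' only, optionally Fisher z-transformed (with |r| clipped at 1 - 1e-7 before
#' the transform).
#'
#' @param ts Frames x ROIs numeric matrix (run-concatenated, aligned with the
#'   motion traces).
#' @param keep Logical vector of retained frames, e.g. the concatenated
#'   `keep` of the subject's censor masks; `NULL` uses every frame.
#' @param fisher_z Return Fisher z values instead of r.
#' @param min_frames Minimum retained frames required (default 3).
#' @return ROI x ROI symmetric matrix (unit diagonal in r mode) with
#'   attributes `subject_id` (if supplied), `n_frames`, `type`, and
#'   `flagged_rois` (ROIs with zero variance over retained frames, whose
#'   edges are `NA`).
#' @export
compute_connectivity <- function(ts, keep = NULL, fisher_z = FALSE,
                                 min_frames = 3L) {
  ts <- as.matrix(ts)
  if (is.null(keep)) keep <- rep(TRUE, nrow(ts))
  if (length(keep) != nrow(ts))
    stop(sprintf("mask length (%d) does not match time-series length (%d)",
                 length(keep), nrow(ts)), call. = FALSE)
  nk <- sum(keep)
  if (nk < min_frames)
    stop(sprintf("only %d retained frames; need at least %d", nk, min_frames),
         call. = FALSE)
  x <- ts[keep, , drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  flagged <- colnames(x)[sds == 0]
  r <- suppressWarnings(stats::cor(x))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  if (fisher_z) {
    r <- atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
  } else {
    diag(r)[!colnames(x) %in% flagged] <- 1
  }
  structure(r, n_frames = nk, type = if (fisher_z) "fisher_z" else "pearson_r",
            flagged_rois = flagged)
}

#' Per-edge QC-FC correlations
#'
#' For each unordered ROI pair, the Pearson correlation across subjects
#' between the subject's mean FD and their connectivity on that edge, paired
#' with the Euclidean distance between the two ROI centers. Subjects with an
#' undefined value on an edge are dropped for that edge, with the remaining
#' count recorded.
#'
#' @param matrices List of connectivity matrices (one per subject, identical
#'   ROI order).
#' @param mean_fd Numeric vector of per-subject mean FD aligned with
#'   `matrices`.
#' @param geometry ROI centroid data frame (`roi_id`, `x`, `y`, `z`) in the
#'   matrices' ROI order.
#' @return Data frame with `roi_a`, `roi_b`, `distance_mm`, `qcfc_r`,
#'   `n_subjects`, `flag` (`"ok"` or `"zero_variance"` for edges constant
#'   across subjects, whose `qcfc_r` is `NA`). Exactly k(k-1)/2 rows for k
#'   ROIs.
#' @export
compute_qcfc <- function(matrices, mean_fd, geometry) {
  n <- length(matrices)
  if (n < 3L) stop("need at least 3 subjects for QC-FC", call. = FALSE)
  if (length(mean_fd) != n)
    stop("mean_fd must align with the connectivity matrices", call. = FALSE)
  if (stats::sd(mean_fd) == 0)
    stop("mean FD is constant across subjects; QC-FC is undefined",
         call. = FALSE)
  k <- nrow(matrices[[1]])
  if (nrow(geometry) != k)
    stop("geometry does not match the connectivity matrix dimension",
         call. = FALSE)
  ut <- upper.tri(matrices[[1]])
  idx <- which(ut, arr.ind = TRUE)
  edges <- vapply(matrices, function(m) m[ut], numeric(sum(ut)))
  # edges: n_edges x n_subjects
  qc <- rep(NA_real_, nrow(edges))
  nsub <- integer(nrow(edges))
  complete <- !is.na(edges)
  nsub <- rowSums(complete)
  all_complete <- nsub == n
  if (any(all_complete)) {
    ce <- t(edges[all_complete, , drop = FALSE])
    sds <- apply(ce, 2, stats::sd)
    qcr <- suppressWarnings(as.numeric(stats::cor(mean_fd, ce)))
    qcr[sds == 0] <- NA_real_
    qc[all_complete] <- qcr
  }
  part <- which(!all_complete & nsub >= 3L)
  for (e in part) {
    ok <- complete[e, ]
    v <- edges[e, ok]
    if (stats::sd(v) == 0 || stats::sd(mean_fd[ok]) == 0) next
    qc[e] <- stats::cor(mean_fd[ok], v)
  }
  D <- as.matrix(stats::dist(geometry[, c("x", "y", "z")]))
  data.frame(roi_a = geometry$roi_id[idx[, 1]],
             roi_b = geometry$roi_id[idx[, 2]],
             distance_mm = D[ut],
             qcfc_r = qc,
             n_subjects = nsub,
             flag = ifelse(is.na(qc), "zero_variance", "ok"),
             stringsAsFactors = FALSE)
}

#' Distance dependence of QC-FC
#'
#' Ordinary least squares of the per-edge QC-FC correlation on inter-ROI
#' Euclidean distance. A nonzero slope indicates that the association between
#' motion and connectivity depends on how far apart regions are — the
#' signature of residual motion artifact. Binned medians over equal-count
#' distance bins are returned for plotting; the slope is always fit on the
#' raw edges.
#'
#' @param edges Data frame from [compute_qcfc()].
#' @param ci_level Confidence level for the slope interval (default 0.99).
#' @param n_bins Number of equal-count distance bins.
#' @return An object of class `qcfc_summary`: list with `slope` (change in
#'   QC-FC per mm), `intercept`, `ci_low`, `ci_high`, `ci_level`, `n_edges`,
#'   `binned_medians` (data frame of bin centers and median QC-FC), and the
#'   `edges` used.
#' @export
qcfc_distance_summary <- function(edges, ci_level = 0.99, n_bins = 10L) {
  ok <- !is.na(edges$qcfc_r)
  e <- edges[ok, , drop = FALSE]
  if (nrow(e) < 2L)
    stop("need at least 2 defined edges for the distance summary",
         call. = FALSE)
  if (length(unique(e$distance_mm)) < 2L)
    stop("need at least 2 distinct distances", call. = FALSE)
  if (stats::sd(e$qcfc_r) == 0) {
    # flat field: the regression is degenerate and the slope is exactly zero
    cf <- c(e$qcfc_r[1], 0)
    ci <- c(0, 0)
  } else {
    fit <- stats::lm(qcfc_r ~ distance_mm, data = e)
    cf <- stats::coef(fit)
    ci <- stats::confint(fit, "distance_mm", level = ci_level)
  }
  n_bins <- max(1L, min(n_bins, nrow(e)))
  br <- unique(stats::quantile(e$distance_mm, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(e$distance_mm, breaks = br, include.lowest = TRUE)
  bm <- data.frame(
    distance_mm = as.numeric(tapply(e$distance_mm, bin, stats::median)),
    median_qcfc = as.numeric(tapply(e$qcfc_r, bin, stats::median)),
    n_edges = as.integer(table(bin)), row.names = NULL)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 ci_low = ci[1], ci_high = ci[2], ci_level = ci_level,
                 n_edges = nrow(e), binned_medians = bm, edges = edges),
            class = "qcfc_summary")
}

#' @export
print.qcfc_summary <- function(x, digits = 4, ...) {
  cat(sprintf("QC-FC distance dependence over %d edges\n", x$n_edges))
  cat(sprintf("  slope: %s per mm, %d%% CI [%s, %s]\n",
              format(x$slope, digits = digits),
              round(100 * x$ci_level),
              format(x$ci_low, digits = digits),
              format(x$ci_high, digits = digits)))
  cat(sprintf("  intercept: %s\n", format(x$intercept, digits = digits)))
  invisible(x)
}

#' @export
plot.qcfc_summary <- function(x, ...) {
  e <- x$edges[!is.na(x$edges$qcfc_r), ]
  graphics::plot(e$distance_mm, e$qcfc_r, pch = 16,
                 col = grDevices::adjustcolor("grey40", alpha.f = 0.25),
                 xlab = "inter-ROI distance (mm)", ylab = "QC-FC (r)", ...)
  graphics::abline(x$intercept, x$slope, col = "firebrick", lwd = 2)
  graphics::points(x$binned_medians$distance_mm,
                   x$binned_medians$median_qcfc, pch = 18, cex = 1.4,
                   col = "dodgerblue4")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Concatenated censor mask for a subject
#'
#' Helper joining per-run censor masks into one frame-aligned logical vector
#' for [compute_connectivity()].
#'
#' @param masks List of `censor_mask` objects in run order.
#' @return Logical vector over the subject's concatenated frames.
#' @export
concat_masks <- function(masks) {
  unlist(lapply(masks, function(m) m$keep), use.names = FALSE)
}
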