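qc_condition_ids <- function() c("T", "C", "0.5", "0.4", "0.3", "R", "0.2", "0.1")

#' Assemble the eight inclusion/exclusion conditions
#'
#' Builds the subjects x conditions exclusion table that pivots the audit:
#'
#' * `T` — tabulated-release pathway: visual-inspection failure flag.
#' * `C` — community-collection pathway: pre-motion processing failure flag.
#' * `0.5`–`0.1` — motion thresholds: excluded in `C` or retaining fewer
#'   than the minimum frames after scrubbing at that threshold.
#' * `R` — recommended-inclusion pathway: segmentation failure and/or fewer
#'   than the minimum frames with FD at or below 0.2 mm.
#'
#' @param records Subject record data frame carrying logical `preqc_fail`,
#'   `visual_fail`, and `seg_fail` columns.
#' @param retention Data frame from [cohort_retention()] with per-subject
#'   per-threshold retained-frame counts.
#' @param thresholds Motion thresholds expected in `retention` (mm).
#' @param min_retained_frames Inclusion minimum (frames).
#' @param recommended_threshold Threshold feeding the `R` condition.
#' @return An object of class `exclusion_table`: data frame with
#'   `subject_id` and one logical exclusion column per condition, in the
#'   order `T, C, 0.5, 0.4, 0.3, R, 0.2, 0.1`.
#' @export
assemble_conditions <- function(records, retention,
                                thresholds = c(0.5, 0.4, 0.3, 0.2, 0.1),
                                min_retained_frames = 375L,
                                recommended_threshold = 0.2) {
  for (fl in c("preqc_fail", "visual_fail", "seg_fail"))
    if (is.null(records[[fl]]))
      stop("records must carry a logical '", fl, "' column", call. = FALSE)
  ids <- records$subject_id
  ret <- list()
  for (th in unique(c(thresholds, recommended_threshold))) {
    sub <- retention[retention$threshold_mm == th, , drop = FALSE]
    missing <- setdiff(ids, sub$subject_id)
    if (length(missing))
      stop(sprintf("retention missing for threshold %.3g mm: %s%s", th,
                   paste(utils::head(missing, 5), collapse = ", "),
                   if (length(missing) > 5) ", ..." else ""), call. = FALSE)
    ret[[as.character(th)]] <-
      sub$n_retained[match(ids, sub$subject_id)]
  }
  tab <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  tab[["T"]] <- as.logical(records$visual_fail)
  tab[["C"]] <- as.logical(records$preqc_fail)
  for (th in thresholds)
    tab[[as.character(th)]] <-
      tab[["C"]] | (ret[[as.character(th)]] < min_retained_frames)
  tab[["R"]] <- as.logical(records$seg_fail) |
    (ret[[as.character(recommended_threshold)]] < min_retained_frames)
  tab <- tab[, c("subject_id", qc_condition_ids()), drop = FALSE]
  class(tab) <- c("exclusion_table", "data.frame")
  tab
}

#' Exclusion counts and percentages per condition
#'
#' @param table An [assemble_conditions()] result (or any data frame with a
#'   `subject_id` column and logical condition columns).
#' @return Data frame with `condition`, `n_excluded`, `pct_excluded`
#'   (percent of the full cohort, reported to one decimal by the print
#'   method).
#' @export
condition_summary <- function(table) {
  conds <- setdiff(names(table), "subject_id")
  n <- nrow(table)
  data.frame(condition = conds,
             n_excluded = vapply(conds, function(cn) sum(table[[cn]]),
                                 numeric(1)),
             pct_excluded = vapply(conds, function(cn)
               100 * mean(table[[cn]]), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Non-overlap between two exclusion conditions
#'
#' Counts subjects excluded under one condition but not the other, the
#' set-difference summary used to show that distinct QC pathways drop
#' different participants.
#'
#' @param table An exclusion table.
#' @param a,b Condition column names.
#' @return Data frame with one row per direction: `excluded_in`,
#'   `not_excluded_in`, `n`.
#' @export
condition_overlap <- function(table, a, b) {
  for (cn in c(a, b))
    if (is.null(table[[cn]]))
      stop("unknown condition: ", cn, call. = FALSE)
  data.frame(excluded_in = c(a, b), not_excluded_in = c(b, a),
             n = c(sum(table[[a]] & !table[[b]]),
                   sum(table[[b]] & !table[[a]])),
             stringsAsFactors = FALSE)
}

#' @export
print.exclusion_table <- function(x, ...) {
  cat(sprintf("Exclusion table: %d subjects x %d conditions\n", nrow(x),
              ncol(x) - 1L))
  s <- condition_summary(x)
  cat(paste(sprintf("  %-4s %5d excluded (%.1f%%)", s$condition,
                    s$n_excluded, s$pct_excluded), collapse = "\n"), "\n")
  invisible(x)
}
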