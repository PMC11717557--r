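threshold_condition_ids <- function() c("0.5", "0.4", "0.3", "0.2", "0.1")

#' Default Bonferroni families for the exclusion models
#'
#' Two families of related predictors are corrected for multiple comparison:
#' the neighborhood characteristics (area disadvantage and child opportunity
#' indices) and the general cognitive ability scores (matrix reasoning, NIH
#' toolbox total composite, NIH toolbox crystallized composite).
#'
#' @return Named list of covariate-name character vectors.
#' @export
default_bonferroni_families <- function() {
  list(neighborhood = c("adi", "coi"),
       cognition = c("wisc_matrix", "nihtb_total", "nihtb_crystallized"))
}

#' Correlate continuous covariates with mean FD within conditions
#'
#' Pearson correlation between each continuous covariate and subjects' mean
#' framewise displacement, computed within each motion condition's analysis
#' sample (subjects not excluded under that condition, by default), with the
#' p-value of the corresponding bivariate linear model.
#'
#' @param records Subject record data frame.
#' @param mean_fd Named numeric vector of per-subject mean FD (mm), e.g. from
#'   [subject_mean_fd()].
#' @param table Exclusion table from [assemble_conditions()]; may be `NULL`
#'   when `sample = "all"`.
#' @param conditions Condition columns to evaluate.
#' @param covariates Continuous covariates to correlate.
#' @param sample `"included"` restricts each condition's correlation to its
#'   retained subjects; `"all"` uses every subject with motion data.
#' @return Data frame with `covariate`, `condition`, `statistic_type`
#'   (`"pearson_r"`), `estimate`, `p_value`, `n`, `flag` (`"ok"` or
#'   `"zero_variance"`).
#' @export
correlate_fd_continuous <- function(records, mean_fd, table = NULL,
                                    conditions = threshold_condition_ids(),
                                    covariates = continuous_covariates(),
                                    sample = c("included", "all")) {
  sample <- match.arg(sample)
  if (sample == "included" && is.null(table))
    stop("an exclusion table is required when sample = 'included'",
         call. = FALSE)
  fd <- mean_fd[records$subject_id]
  out <- list()
  for (cond in conditions) {
    in_sample <- if (sample == "included") !table[[cond]][match(records$subject_id, table$subject_id)]
    else rep(TRUE, nrow(records))
    for (cv in covariates) {
      x <- records[[cv]][in_sample]
      y <- fd[in_sample]
      ok <- stats::complete.cases(x, y)
      x <- x[ok]; y <- y[ok]
      if (length(x) < 3L)
        stop(sprintf("fewer than 3 complete pairs for '%s' in condition %s",
                     cv, cond), call. = FALSE)
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        out[[length(out) + 1L]] <- data.frame(
          covariate = cv, condition = cond, statistic_type = "pearson_r",
          estimate = NA_real_, p_value = NA_real_, n = length(x),
          flag = "zero_variance", stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(x, y)
      out[[length(out) + 1L]] <- data.frame(
        covariate = cv, condition = cond, statistic_type = "pearson_r",
        estimate = unname(ct$estimate), p_value = ct$p.value, n = length(x),
        flag = "ok", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Categorical contrasts of mean FD
#'
#' Bivariate linear models of standardized mean FD on each categorical
#' covariate, returning per-level standardized coefficients against the
#' study reference levels together with the omnibus F-test p-value. FD is
#' standardized within each condition's analysis sample.
#'
#' @inheritParams correlate_fd_continuous
#' @param covariates Categorical covariates to contrast.
#' @return Data frame with `covariate`, `condition`, `contrast_label`,
#'   `statistic_type` (`"standardized_beta"`), `estimate`, `p_value`,
#'   `omnibus_p`, `n`.
#' @export
contrast_fd_categorical <- function(records, mean_fd, table = NULL,
                                    conditions = threshold_condition_ids(),
                                    covariates = categorical_covariates(),
                                    sample = c("included", "all")) {
  sample <- match.arg(sample)
  if (sample == "included" && is.null(table))
    stop("an exclusion table is required when sample = 'included'",
         call. = FALSE)
  fd <- mean_fd[records$subject_id]
  refs <- covariate_reference_levels()
  out <- list()
  for (cond in conditions) {
    in_sample <- if (sample == "included") !table[[cond]][match(records$subject_id, table$subject_id)]
    else rep(TRUE, nrow(records))
    for (cv in covariates) {
      x <- droplevels(factor(records[[cv]][in_sample]))
      y <- fd[in_sample]
      ok <- stats::complete.cases(x, y)
      x <- droplevels(x[ok]); y <- y[ok]
      if (nlevels(x) < 2L)
        stop(sprintf("covariate '%s' has a single level in condition %s", cv,
                     cond), call. = FALSE)
      ref <- refs[[cv]]
      if (!is.null(ref) && !ref %in% levels(x))
        stop(sprintf("reference level '%s' absent for covariate '%s'", ref, cv),
             call. = FALSE)
      if (!is.null(ref)) x <- stats::relevel(x, ref = ref)
      z <- as.numeric(scale(y))
      fit <- stats::lm(z ~ x)
      sm <- stats::summary.lm(fit)$coefficients
      omnibus <- stats::anova(fit)[["Pr(>F)"]][1]
      terms <- rownames(sm)[-1]
      lab <- sub("^x", "", terms)
      out[[length(out) + 1L]] <- data.frame(
        covariate = cv, condition = cond,
        contrast_label = paste0(lab, " — ", levels(x)[1]),
        statistic_type = "standardized_beta",
        estimate = sm[-1, 1], p_value = sm[-1, 4],
        omnibus_p = omnibus, n = length(z),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

relevel_records <- function(records, covariates) {
  refs <- covariate_reference_levels()
  for (cv in intersect(covariates, names(refs))) {
    x <- factor(records[[cv]])
    if (!refs[[cv]] %in% levels(x))
      stop(sprintf("reference level '%s' absent for covariate '%s'",
                   refs[[cv]], cv), call. = FALSE)
    records[[cv]] <- stats::relevel(x, ref = refs[[cv]])
  }
  records
}

or_rows_from_glm <- function(fit, covariate, condition, ci_level, adjusted,
                             method) {
  sm <- stats::coef(summary(fit))
  est <- sm[, 1]; se <- sm[, 2]; p <- sm[, 4]
  flag <- "ok"
  if (!fit$converged || any(se > 50) || any(abs(est) > 15)) flag <- "separation"
  if (method == "profile" && flag == "ok") {
    if (!requireNamespace("MASS", quietly = TRUE))
      stop("profile confidence intervals require the MASS package",
           call. = FALSE)
    ci <- suppressMessages(stats::confint(fit, level = ci_level))
    if (is.null(dim(ci))) ci <- matrix(ci, nrow = 1)
    lo <- ci[, 1]; hi <- ci[, 2]
  } else {
    zq <- stats::qnorm(1 - (1 - ci_level) / 2)
    lo <- est - zq * se; hi <- est + zq * se
  }
  or <- exp(est)
  if (flag == "separation") {
    or[] <- NA_real_; lo[] <- NA_real_; hi[] <- NA_real_
  } else {
    lo <- exp(lo); hi <- exp(hi)
  }
  data.frame(covariate = covariate, term = rownames(sm),
             condition = condition, odds_ratio = unname(or),
             ci_low = unname(lo), ci_high = unname(hi),
             ci_level = ci_level, p_value = unname(p),
             adjusted = adjusted, flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bivariate (unconditional) exclusion models
#'
#' One logistic regression of exclusion status on each covariate separately,
#' within each condition; with the default eight conditions and 17 covariates
#' this is the full set of unconditional missingness models. Categorical
#' covariates expand to reference-coded terms. Odds ratios are exponentiated
#' coefficients with Wald confidence intervals at `ci_level` (90% by
#' default); `method = "profile"` substitutes profile-likelihood intervals.
#'
#' @param records Subject record data frame.
#' @param table Exclusion table.
#' @param conditions Condition columns to model.
#' @param covariates Covariates to model (default all 17). An empty character
#'   vector fits intercept-only models, whose exponentiated intercept is the
#'   exclusion odds.
#' @param ci_level Confidence level for the odds-ratio intervals.
#' @param method Interval construction, `"wald"` or `"profile"`.
#' @return Data frame of odds-ratio results: `covariate`, `term`,
#'   `condition`, `odds_ratio`, `ci_low`, `ci_high`, `ci_level`, `p_value`,
#'   `adjusted` (FALSE), `flag` (`"ok"` or `"separation"`, the latter with
#'   estimates withheld).
#' @export
fit_bivariate_exclusion <- function(records, table,
                                    conditions = qc_condition_ids(),
                                    covariates = analysis_covariates(),
                                    ci_level = 0.90,
                                    method = c("wald", "profile")) {
  method <- match.arg(method)
  conditions <- intersect(conditions, names(table))
  out <- list()
  for (cond in conditions) {
    y_all <- as.numeric(table[[cond]][match(records$subject_id,
                                            table$subject_id)])
    if (length(unique(y_all[!is.na(y_all)])) < 2L)
      stop(sprintf("condition %s has a single outcome class", cond),
           call. = FALSE)
    if (!length(covariates)) {
      fit <- stats::glm(y_all ~ 1, family = stats::binomial())
      out[[length(out) + 1L]] <-
        or_rows_from_glm(fit, "(Intercept)", cond, ci_level, FALSE, method)
      next
    }
    for (cv in covariates) {
      dat <- data.frame(y = y_all, x = records[[cv]])
      dat <- dat[stats::complete.cases(dat), , drop = FALSE]
      dat <- relevel_records(stats::setNames(dat, c("y", cv)), cv)
      fml <- stats::as.formula(paste("y ~", cv))
      # separation and non-convergence are detected and flagged downstream
      fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                         data = dat))
      rows <- or_rows_from_glm(fit, cv, cond, ci_level, FALSE, method)
      rows <- rows[rows$term != "(Intercept)", , drop = FALSE]
      out[[length(out) + 1L]] <- rows
    }
  }
  do.call(rbind, out)
}

#' Adjusted (single-step) exclusion models
#'
#' One logistic regression per condition with all covariates entered in a
#' single step, optionally controlling for collection site and scanner.
#' Complete cases across all predictors are used.
#'
#' @inheritParams fit_bivariate_exclusion
#' @param include_site,include_scanner Add site / scanner categories to the
#'   model.
#' @return Data frame as in [fit_bivariate_exclusion()] with
#'   `adjusted = TRUE`; intercept rows are included.
#' @export
fit_adjusted_exclusion <- function(records, table,
                                   conditions = qc_condition_ids(),
                                   covariates = analysis_covariates(),
                                   ci_level = 0.90,
                                   include_site = FALSE,
                                   include_scanner = FALSE,
                                   method = c("wald", "profile")) {
  method <- match.arg(method)
  conditions <- intersect(conditions, names(table))
  preds <- covariates
  if (include_site) preds <- c(preds, "site")
  if (include_scanner) preds <- c(preds, "scanner")
  records <- relevel_records(records, covariates)
  out <- list()
  for (cond in conditions) {
    dat <- records[, c("subject_id", preds), drop = FALSE]
    dat$y <- as.numeric(table[[cond]][match(dat$subject_id,
                                            table$subject_id)])
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    if (length(unique(dat$y)) < 2L)
      stop(sprintf("condition %s has a single outcome class", cond),
           call. = FALSE)
    refs <- covariate_reference_levels()
    for (p in preds) {
      if (!is.factor(dat[[p]])) next
      dat[[p]] <- droplevels(dat[[p]])
      if (p %in% names(refs) && !refs[[p]] %in% levels(dat[[p]]))
        stop(sprintf("reference level '%s' absent for covariate '%s' in condition %s",
                     refs[[p]], p, cond), call. = FALSE)
    }
    fml <- stats::as.formula(paste("y ~", paste(preds, collapse = " + ")))
    fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                       data = dat))
    if (anyNA(stats::coef(fit)))
      stop("design matrix is rank deficient; aliased terms: ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "), call. = FALSE)
    cov_of_term <- function(terms) {
      hit <- rep("(Intercept)", length(terms))
      for (p in preds) hit[startsWith(terms, p)] <- p
      hit
    }
    rows <- or_rows_from_glm(fit, NA_character_, cond, ci_level, TRUE, method)
    rows$covariate <- cov_of_term(rows$term)
    out[[length(out) + 1L]] <- rows
  }
  do.call(rbind, out)
}

#' Bonferroni correction within predictor families
#'
#' Multiplies p-values by the family size (capped at 1) for covariates that
#' belong to a declared family; covariates outside every family are left
#' unchanged.
#'
#' @param results Odds-ratio (or association) data frame with `covariate`
#'   and `p_value` columns.
#' @param families Named list mapping family label to covariate names; each
#'   covariate may appear in at most one family.
#' @return `results` with added `corrected_family` and `p_corrected`
#'   columns.
#' @export
apply_bonferroni <- function(results, families = default_bonferroni_families()) {
  all_members <- unlist(families, use.names = FALSE)
  if (anyDuplicated(all_members))
    stop("each covariate may appear in at most one family", call. = FALSE)
  unknown <- setdiff(all_members, unique(results$covariate))
  if (length(unknown))
    stop("unknown covariate(s) in family spec: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  results$corrected_family <- NA_character_
  results$p_corrected <- results$p_value
  for (fam in names(families)) {
    members <- families[[fam]]
    hit <- results$covariate %in% members
    results$corrected_family[hit] <- fam
    results$p_corrected[hit] <- pmin(1, results$p_value[hit] * length(members))
  }
  results
}

#' Define a subgroup for the excess-missingness trajectory
#'
#' @param covariate Covariate name.
#' @param level For categorical covariates, the level defining the group.
#' @param cut For continuous covariates, the standardized cut point
#'   (default 1.5 SD).
#' @param direction `"above"` (z >= cut), `"below"` (z <= -cut), or `"abs"`
#'   (|z| >= cut).
#' @param label Optional display label.
#' @return A group specification list for
#'   [excess_missingness_trajectory()].
#' @export
trajectory_group <- function(covariate, level = NULL, cut = 1.5,
                             direction = c("above", "below", "abs"),
                             label = NULL) {
  direction <- match.arg(direction)
  if (is.null(label)) {
    label <- if (!is.null(level)) paste0(covariate, "=", level)
    else paste0(covariate, switch(direction, above = paste0(" z>=", cut),
                                  below = paste0(" z<=-", cut),
                                  abs = paste0(" |z|>=", cut)))
  }
  list(covariate = covariate, level = level, cut = cut,
       direction = direction, label = label)
}

#' Excess missingness across conditions
#'
#' For each condition and subgroup: the subgroup's exclusion percentage minus
#' the whole-sample exclusion percentage (percentage points), plotted against
#' the overall percentage of data excluded. At the endpoints — a condition
#' excluding nobody or everybody — the excess is exactly zero for every
#' group.
#'
#' @param records Subject record data frame.
#' @param table Exclusion table.
#' @param groups List of [trajectory_group()] specifications.
#' @param conditions Condition columns to trace.
#' @return Data frame with `group`, `condition`, `pct_data_excluded`
#'   (overall), `group_pct_excluded`, `excess` (percentage points), ordered
#'   by `pct_data_excluded` within group. Empty groups are dropped with a
#'   warning.
#' @export
excess_missingness_trajectory <- function(records, table, groups,
                                          conditions = qc_condition_ids()) {
  conditions <- intersect(conditions, names(table))
  y <- table[match(records$subject_id, table$subject_id), conditions,
             drop = FALSE]
  out <- list()
  for (g in groups) {
    v <- records[[g$covariate]]
    if (is.null(v))
      stop("unknown covariate in group spec: ", g$covariate, call. = FALSE)
    member <- if (!is.null(g$level)) {
      !is.na(v) & v == g$level
    } else {
      z <- as.numeric(scale(as.numeric(v)))
      switch(g$direction,
             above = !is.na(z) & z >= g$cut,
             below = !is.na(z) & z <= -g$cut,
             abs = !is.na(z) & abs(z) >= g$cut)
    }
    if (!any(member)) {
      warning("empty trajectory group dropped: ", g$label, call. = FALSE)
      next
    }
    overall <- 100 * colMeans(y)
    grp <- 100 * colMeans(y[member, , drop = FALSE])
    out[[length(out) + 1L]] <- data.frame(
      group = g$label, condition = conditions,
      pct_data_excluded = unname(overall),
      group_pct_excluded = unname(grp),
      excess = unname(grp - overall),
      row.names = NULL, stringsAsFactors = FALSE)[order(overall), ]
  }
  do.call(rbind, out)
}

#' Covariate missingness report
#'
#' Counts and percentages of missing values per covariate, the style of
#' summary used alongside the exclusion tables.
#'
#' @param records Subject record data frame.
#' @param covariates Covariates to report.
#' @return Data frame with `covariate`, `n_missing`, `pct_missing`.
#' @export
covariate_missingness <- function(records,
                                  covariates = analysis_covariates()) {
  data.frame(covariate = covariates,
             n_missing = vapply(covariates, function(cv)
               sum(is.na(records[[cv]])), numeric(1)),
             pct_missing = vapply(covariates, function(cv)
               100 * mean(is.na(records[[cv]])), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
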