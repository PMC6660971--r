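# Audit of failed texture computations: compare cases where a family
# failed vs. succeeded using the always-available histogram and shape
# features, and turn the non-error group's confidence intervals into
# minimum-nodule-size guidelines.

AUDIT_SHAPE_7 <- paste0("shape3d.", c("volume", "max_diameter_3d",
                                      "surface_area", "surface_volume_ratio",
                                      "compactness", "sphericity",
                                      "spherical_disproportion"))

audit_feature_names <- function() {
  c(paste("hist.whole", HIST_NAMES_19, sep = "."), AUDIT_SHAPE_7)
}

audit_family_cols <- function(tab, family = c("ngtdm", "subsampled_glcm")) {
  family <- match.arg(family)
  prefix <- if (family == "ngtdm") "^ngtdm\\." else "^glcmsub\\."
  grep(prefix, feature_cols(tab), value = TRUE)
}

#' Split cases into error / non-error groups for a texture family
#'
#' A case is in the error group iff at least one feature of the family
#' failed to compute.
#'
#' @param tab a [feature_table()] containing the family's columns.
#' @param family `"ngtdm"` or `"subsampled_glcm"`.
#' @return list with `error` and `nonerror` case-id vectors.
#' @export
split_error_groups <- function(tab, family = c("ngtdm", "subsampled_glcm")) {
  family <- match.arg(family)
  cols <- audit_family_cols(tab, family)
  if (!length(cols))
    stop("table has no columns of the audited family", call. = FALSE)
  failed <- apply(is.na(tab[cols]), 1, any)
  list(error = tab$case_id[failed], nonerror = tab$case_id[!failed])
}

#' Compare error and non-error groups feature by feature
#'
#' Welch one-tailed t-tests on 26 features (19 whole-ROI histogram + 7
#' shape); the 95% CI of the non-error group mean is
#' mean +/- t(0.975, n-1) sd / sqrt(n). With `direction = "auto"` the
#' tested direction follows the sign of the observed mean difference —
#' convenient for exploration, but the realized type-I rate of the
#' directional decision is then that of a two-sided test at twice the
#' level. A fixed direction gives a calibrated one-tailed test.
#'
#' @param tab feature table.
#' @param groups a [split_error_groups()] result.
#' @param features audited features (default: the 26-feature panel).
#' @param direction `"auto"`, `"nonerror_greater"` or `"error_greater"`.
#' @return data.frame of class `failure_audit`: one row per testable
#'   feature with group means, Welch t, one-sided p, CI bounds and the
#'   tested direction.
#' @export
compare_groups <- function(tab, groups, features = audit_feature_names(),
                           direction = c("auto", "nonerror_greater",
                                         "error_greater")) {
  direction <- match.arg(direction)
  features <- intersect(features, feature_cols(tab))
  ie <- match(groups$error, tab$case_id)
  io <- match(groups$nonerror, tab$case_id)
  if (length(ie) < 3L || length(io) < 3L)
    stop("comparison skipped: need >= 3 cases per group", call. = FALSE)
  rows <- lapply(features, function(f) {
    xe <- tab[[f]][ie]; xo <- tab[[f]][io]
    xe <- xe[is.finite(xe)]; xo <- xo[is.finite(xo)]
    if (length(xe) < 3L || length(xo) < 3L) return(NULL)
    if (sd(xe) == 0 && sd(xo) == 0) return(NULL)  # zero variance: skip
    dir <- if (direction == "auto") {
      if (mean(xo) > mean(xe)) "nonerror_greater" else "error_greater"
    } else direction
    tt <- stats::t.test(xo, xe,
                        alternative = if (dir == "nonerror_greater") "greater" else "less")
    n <- length(xo)
    half <- qt(0.975, n - 1) * sd(xo) / sqrt(n)
    data.frame(feature = f,
               mean_error = mean(xe), mean_nonerror = mean(xo),
               t_statistic = unname(tt$statistic),
               one_sided_p = tt$p.value,
               ci95_lo = mean(xo) - half, ci95_hi = mean(xo) + half,
               direction_tested = dir,
               n_error = length(xe), n_nonerror = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("failure_audit", class(out))
  out
}

#' Minimum-size guidelines from the audit comparisons
#'
#' For each size-related feature where the non-error group is larger, the
#' guideline is the lower bound of the 95% CI of the non-error mean,
#' rounded down to `precision`.
#'
#' @param comparisons a [compare_groups()] result.
#' @param features size-related features to convert into guidelines.
#' @param precision rounding-down grid of the published bound.
#' @return data.frame with the raw CI lower bound and the rounded
#'   guideline per feature.
#' @export
recommend_thresholds <- function(comparisons,
                                 features = c("shape3d.volume",
                                              "shape3d.max_diameter_3d",
                                              "shape3d.surface_area"),
                                 precision = 10) {
  cmp <- comparisons[comparisons$feature %in% features &
                       comparisons$direction_tested == "nonerror_greater", ,
                     drop = FALSE]
  if (nrow(cmp) == 0L)
    return(data.frame(feature = character(), ci95_lo = numeric(),
                      guideline = numeric()))
  data.frame(feature = cmp$feature,
             ci95_lo = cmp$ci95_lo,
             guideline = floor(cmp$ci95_lo / precision) * precision,
             stringsAsFactors = FALSE)
}

#' Run the full failure audit for one family
#'
#' @param tab feature table (must include the audited family plus the
#'   histogram and shape families).
#' @param family `"ngtdm"` or `"subsampled_glcm"`.
#' @param precision guideline rounding grid.
#' @return list with `groups`, `comparisons` and `guidelines`; NULL
#'   comparisons (with a warning) when one group is empty.
#' @export
run_failure_audit <- function(tab, family = c("ngtdm", "subsampled_glcm"),
                              precision = 10) {
  family <- match.arg(family)
  groups <- split_error_groups(tab, family)
  if (length(groups$error) == 0L || length(groups$nonerror) == 0L) {
    warning("all cases fall in one group; comparison skipped")
    return(list(family = family, groups = groups, comparisons = NULL,
                guidelines = NULL))
  }
  cmp <- compare_groups(tab, groups)
  list(family = family, groups = groups, comparisons = cmp,
       guidelines = recommend_thresholds(cmp, precision = precision))
}
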