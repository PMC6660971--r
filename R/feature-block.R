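# A feature block is the unit each family returns: parallel named vectors
# of values and failure reasons. A value is NA iff its failure reason is
# not "none"; failures are recorded, never raised.

FAILURE_REASONS <- c("none", "empty_roi", "too_few_voxels",
                     "degenerate_matrix", "fit_nonconvergence")

new_feature_block <- function() {
  list(values = numeric(0), failure = character(0))
}

fb_add <- function(blk, values) {
  stopifnot(!is.null(names(values)))
  bad <- !is.finite(values)
  failure <- rep("none", length(values))
  if (any(bad)) {
    values[bad] <- NA_real_
    failure[bad] <- "degenerate_matrix"
  }
  blk$values <- c(blk$values, values)
  blk$failure <- c(blk$failure, setNames(failure, names(values)))
  blk
}

fb_fail <- function(blk, nms, reason) {
  stopifnot(reason %in% FAILURE_REASONS, reason != "none")
  blk$values <- c(blk$values, setNames(rep(NA_real_, length(nms)), nms))
  blk$failure <- c(blk$failure, setNames(rep(reason, length(nms)), nms))
  blk
}

fb_concat <- function(...) {
  blks <- list(...)
  list(values = do.call(c, lapply(blks, `[[`, "values")),
       failure = do.call(c, lapply(blks, `[[`, "failure")))
}

#' Specify discretization settings for the feature panel
#'
#' Histogram features discretize over the fixed CT range (4096 bins give
#' 1 HU per bin); GLCM and ISZM discretize equal-width over the per-ROI
#' min–max.
#'
#' @param histogram_bins histogram bin count (default 4096).
#' @param glcm_bins GLCM gray-level count (default 256).
#' @param iszm_bins ISZM gray-level count (default 32; shared with NGTDM).
#' @param histogram_range fixed HU interval for histogram binning.
#' @return list of class `binning_spec`.
#' @export
binning_spec <- function(histogram_bins = 4096, glcm_bins = 256,
                         iszm_bins = 32,
                         histogram_range = c(-1024, 3071)) {
  stopifnot(histogram_bins >= 2, glcm_bins >= 2, iszm_bins >= 2,
            length(histogram_range) == 2, diff(histogram_range) > 0)
  structure(list(histogram_bins = as.integer(histogram_bins),
                 glcm_bins = as.integer(glcm_bins),
                 iszm_bins = as.integer(iszm_bins),
                 histogram_range = as.numeric(histogram_range)),
            class = "binning_spec")
}
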