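# First-order (histogram) features. Energy is voxel-count normalized
# (mean squared intensity) so that inner/outer/delta comparisons contrast
# densities rather than region sizes. Entropy and uniformity are computed on
# a histogram with a fixed HU range [-1024, 3071], so the default 4096 bins
# give exactly 1 HU per bin; all logarithms in the package are base 2 with
# 0 * log2(0) := 0. Kurtosis is uncorrected (normal = 3), skewness is the
# standardized third moment.

HIST_NAMES_19 <- c("mean", "sd", "variance", "skewness", "kurtosis",
                   "min", "max", "range", "median", "p10", "p25", "p75",
                   "p90", "iqr", "energy", "entropy", "uniformity",
                   "rms", "mad")
HIST_NAMES_9  <- c("mean", "sd", "skewness", "kurtosis", "min", "max",
                   "median", "energy", "entropy")
HIST_NAMES_14 <- setdiff(HIST_NAMES_19, c("variance", "mad", "p10", "p90", "rms"))

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Histogram features of an intensity sample
#'
#' @param x numeric vector of HU intensities from an ROI.
#' @param bins a [binning_spec()] (uses `histogram_bins` and
#'   `histogram_range`).
#' @return named numeric vector of 19 values.
#' @export
histogram_features <- function(x, bins = binning_spec()) {
  n <- length(x)
  if (n == 0L) stop("empty ROI", call. = FALSE)
  m <- mean(x)
  s2 <- if (n > 1) var(x) else 0
  s <- sqrt(s2)
  cx <- x - m
  m2 <- mean(cx^2)
  skew <- if (m2 > 0) mean(cx^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean(cx^4) / m2^2 else 0
  q <- quantile(x, c(0.10, 0.25, 0.5, 0.75, 0.90), names = FALSE, type = 7)
  b <- bin_intensities(x, bins$histogram_bins,
                       lo = bins$histogram_range[1], hi = bins$histogram_range[2])
  p <- tabulate(b, nbins = bins$histogram_bins) / n
  c(mean = m, sd = s, variance = s2, skewness = skew, kurtosis = kurt,
    min = min(x), max = max(x), range = max(x) - min(x), median = q[3],
    p10 = q[1], p25 = q[2], p75 = q[4], p90 = q[5], iqr = q[4] - q[2],
    energy = mean(x^2), entropy = entropy_bits(p),
    uniformity = sum(p^2), rms = sqrt(mean(x^2)),
    mad = mean(abs(cx)))
}

hist_named <- function(x, bins, roi, keep) {
  v <- histogram_features(x, bins)[keep]
  names(v) <- paste("hist", roi, keep, sep = ".")
  v
}

#' Histogram family over the ROI partition (60 features)
#'
#' 19 whole-ROI features, 14 positive-voxel features, 9 inner, 9 outer and
#' 9 delta (outer minus inner) features. Failures follow the per-family
#' contract: an empty positive mask fails the 14 positive features; a
#' degenerate partition fails inner/outer/delta.
#'
#' @param partition a [partition_roi()] result.
#' @param volume the intensity array of the case.
#' @param bins a [binning_spec()].
#' @return A `feature_block` (named values + failure reasons).
#' @export
histogram_family <- function(partition, volume, bins = binning_spec()) {
  blk <- new_feature_block()
  blk <- fb_add(blk, hist_named(volume[partition$whole], bins, "whole", HIST_NAMES_19))
  if (sum(partition$positive) > 0L) {
    blk <- fb_add(blk, hist_named(volume[partition$positive], bins, "pos", HIST_NAMES_14))
  } else {
    blk <- fb_fail(blk, paste("hist.pos", HIST_NAMES_14, sep = "."), "empty_roi")
  }
  io_names <- c(paste("hist.inner", HIST_NAMES_9, sep = "."),
                paste("hist.outer", HIST_NAMES_9, sep = "."),
                paste("hist.delta", HIST_NAMES_9, sep = "."))
  if (partition$degenerate || sum(partition$outer) == 0L ||
      sum(partition$inner) == 0L) {
    blk <- fb_fail(blk, io_names, "empty_roi")
  } else {
    vin <- histogram_features(volume[partition$inner], bins)[HIST_NAMES_9]
    vout <- histogram_features(volume[partition$outer], bins)[HIST_NAMES_9]
    blk <- fb_add(blk, setNames(vin, paste("hist.inner", HIST_NAMES_9, sep = ".")))
    blk <- fb_add(blk, setNames(vout, paste("hist.outer", HIST_NAMES_9, sep = ".")))
    blk <- fb_add(blk, setNames(vout - vin, paste("hist.delta", HIST_NAMES_9, sep = ".")))
  }
  blk
}
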