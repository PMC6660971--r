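# Intensity size zone matrix: 26-connected components of equal binned
# intensity, tallied into a (iszm_bins x 256) matrix of intensity bin by
# zone size (sizes above 256 accumulate in the last column).

ISZM_NAMES <- c("iszm.zone_percentage", "iszm.large_zone_emphasis")
ISZM_SIZE_CAP <- 256L

#' Intensity size zone matrix of an ROI
#'
#' @param volume intensity array.
#' @param roi logical ROI on the same grid.
#' @param bins number of intensity bins (default 32).
#' @param size_cap zone sizes above this accumulate in the last column.
#' @return `bins` x `size_cap` count matrix.
#' @export
iszm_matrix <- function(volume, roi, bins = 32, size_cap = ISZM_SIZE_CAP) {
  stopifnot(any(roi))
  bb <- mask_bbox(roi)                         # zones are confined to the bbox
  volume <- crop_bbox(volume, bb)
  roi <- crop_bbox(roi, bb)
  lv <- array(0L, dim(roi))
  lv[roi] <- bin_intensities(volume[roi], bins)
  Z <- matrix(0, bins, size_cap)
  for (b in sort(unique(lv[roi]))) {
    cc <- label_components26(lv == b)
    if (cc$n == 0L) next
    sizes <- tabulate(cc$labels[cc$labels > 0L], nbins = cc$n)
    sizes <- pmin(sizes, size_cap)
    tab <- tabulate(sizes, nbins = size_cap)
    Z[b, ] <- Z[b, ] + tab
  }
  Z
}

#' ISZM features (2 values)
#'
#' Zone percentage (number of zones over number of ROI voxels) and
#' large-zone emphasis (size^2-weighted mean over zones, sizes capped).
#'
#' @param volume intensity array.
#' @param roi logical ROI.
#' @param bins a [binning_spec()] (uses `iszm_bins`).
#' @return A `feature_block` of 2 values.
#' @export
iszm_features <- function(volume, roi, bins = binning_spec()) {
  blk <- new_feature_block()
  if (!any(roi)) return(fb_fail(blk, ISZM_NAMES, "empty_roi"))
  Z <- iszm_matrix(volume, roi, bins$iszm_bins)
  nz <- sum(Z)
  s <- matrix(seq_len(ncol(Z)), nrow(Z), ncol(Z), byrow = TRUE)
  fb_add(blk, setNames(c(nz / sum(roi), sum(Z * s^2) / nz), ISZM_NAMES))
}
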