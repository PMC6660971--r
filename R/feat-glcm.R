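# Gray-level co-occurrence features. Intensities are binned equal-width
# over the ROI min-max; co-occurrences are pooled over the 13 unique 3D
# index-space directions at Chebyshev distance 1 and symmetrized, giving
# one normalized matrix per ROI. Eleven Haralick-style measures are
# computed on whole, inner and outer ROIs plus their elementwise delta;
# a second "sub-sampled" variant first block-down-samples the grid by 2.

GLCM_MEASURES <- c("energy", "entropy", "contrast", "homogeneity",
                   "dissimilarity", "correlation", "cluster_shade",
                   "cluster_prominence", "cluster_tendency",
                   "difference_entropy", "imc1")

#' Build a pooled, symmetric, normalized GLCM for an ROI
#'
#' @param volume intensity array.
#' @param roi logical array selecting the ROI on the same grid.
#' @param bins number of gray levels (equal-width over the ROI min-max).
#' @return `glcm_bins` x `glcm_bins` matrix summing to 1, or `NULL` when no
#'   in-ROI neighbour pair exists (degenerate matrix).
#' @export
glcm_matrix <- function(volume, roi, bins = 256) {
  n <- sum(roi)
  if (n < 2L) return(NULL)
  bb <- mask_bbox(roi)                         # pairs live inside the bbox
  volume <- crop_bbox(volume, bb)
  roi <- crop_bbox(roi, bb)
  vals <- volume[roi]
  lv <- array(NA_integer_, dim(roi))
  lv[roi] <- bin_intensities(vals, bins)
  dirs <- glcm_directions13()
  is <- vector("list", nrow(dirs))
  js <- vector("list", nrow(dirs))
  for (r in seq_len(nrow(dirs))) {
    nb <- shift3(lv, -dirs[r, ], NA_integer_)  # neighbour at +dir
    ok <- !is.na(lv) & !is.na(nb)
    is[[r]] <- lv[ok]
    js[[r]] <- nb[ok]
  }
  i <- unlist(is); j <- unlist(js)
  if (!length(i)) return(NULL)
  counts <- tabulate(i + (j - 1L) * bins, nbins = bins * bins)
  P <- matrix(counts, bins, bins)
  P <- P + t(P)                                # symmetric (adds opposites)
  P / sum(P)
}

#' Haralick-style measures of a normalized GLCM (11 values)
#'
#' Energy, entropy, contrast, homogeneity (inverse difference),
#' dissimilarity, correlation, cluster shade/prominence/tendency,
#' difference entropy (entropy of P_(x-y)) and the first informational
#' measure of correlation. Logs are base 2 with 0 log 0 := 0; the
#' correlation of a single-level matrix is defined as 1 and IMC1 as 0.
#'
#' @param P normalized symmetric GLCM.
#' @return named numeric vector of 11 values.
#' @export
glcm_features <- function(P) {
  B <- nrow(P)
  i <- matrix(seq_len(B), B, B)
  j <- t(i)
  px <- rowSums(P)
  mu <- sum(seq_len(B) * px)
  sig2 <- sum((seq_len(B) - mu)^2 * px)
  sig <- sqrt(sig2)
  pd <- as.vector(rowsum(as.vector(P), as.vector(abs(i - j))))
  energy <- sum(P^2)
  entropy <- entropy_bits(as.vector(P))
  contrast <- sum((i - j)^2 * P)
  homogeneity <- sum(P / (1 + abs(i - j)))
  dissimilarity <- sum(abs(i - j) * P)
  correlation <- if (sig2 > 0) sum((i - mu) * (j - mu) * P) / sig2 else 1
  csum <- i + j - 2 * mu
  cluster_shade <- sum(csum^3 * P)
  cluster_prominence <- sum(csum^4 * P)
  cluster_tendency <- sum(csum^2 * P)
  difference_entropy <- entropy_bits(pd)
  hx <- entropy_bits(px)
  if (hx > 0) {
    # by symmetry sum P(i,j) (log px_i + log px_j) = 2 sum px log px
    nzp <- px > 0
    hxy1 <- -2 * sum(px[nzp] * log2(px[nzp]))
    imc1 <- (entropy - hxy1) / hx
  } else imc1 <- 0
  setNames(c(energy, entropy, contrast, homogeneity, dissimilarity,
             correlation, cluster_shade, cluster_prominence,
             cluster_tendency, difference_entropy, imc1),
           GLCM_MEASURES)
}

# Block-down-sample by 2 per axis: mean pooling of intensities, majority
# pooling of the mask (ties count as foreground when >= half the pooled
# voxels present are foreground).
block_downsample2 <- function(volume, mask) {
  dm <- dim(volume)
  out_dim <- pmax(1L, ceiling(dm / 2))
  vol <- array(0, out_dim)
  cnt <- array(0, out_dim)
  fg <- array(0, out_dim)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    if (1 + dx > dm[1] || 1 + dy > dm[2] || 1 + dz > dm[3]) next
    ix <- seq(1 + dx, dm[1], by = 2)
    iy <- seq(1 + dy, dm[2], by = 2)
    iz <- seq(1 + dz, dm[3], by = 2)
    tx <- (ix + 1) %/% 2; ty <- (iy + 1) %/% 2; tz <- (iz + 1) %/% 2
    vol[tx, ty, tz] <- vol[tx, ty, tz] + volume[ix, iy, iz]
    cnt[tx, ty, tz] <- cnt[tx, ty, tz] + 1
    fg[tx, ty, tz] <- fg[tx, ty, tz] + mask[ix, iy, iz]
  }
  list(volume = vol / pmax(cnt, 1), mask = fg >= cnt / 2 & fg > 0)
}

glcm_roi_block <- function(volume, roi, bins, prefix) {
  nms <- paste(prefix, GLCM_MEASURES, sep = ".")
  P <- glcm_matrix(volume, roi, bins)
  if (is.null(P)) {
    blk <- fb_fail(new_feature_block(), nms, "degenerate_matrix")
    attr(blk, "ok") <- FALSE
  } else {
    blk <- fb_add(new_feature_block(), setNames(glcm_features(P), nms))
    attr(blk, "ok") <- TRUE
  }
  blk
}

#' GLCM family over the ROI partition (44 values per sampling type)
#'
#' Eleven measures on the whole, inner and outer ROIs plus the elementwise
#' outer-minus-inner delta. With `subsample = TRUE` the grid is first
#' block-down-sampled by 2 per axis (mean-pooled intensities,
#' majority-pooled mask) — the dominant failure mode for small nodules.
#'
#' @param partition a [partition_roi()] result.
#' @param volume intensity array.
#' @param bins a [binning_spec()] (uses `glcm_bins`).
#' @param subsample compute the sub-sampled variant.
#' @return A `feature_block` of 44 values.
#' @export
glcm_family <- function(partition, volume, bins = binning_spec(),
                        subsample = FALSE) {
  prefix <- if (subsample) "glcmsub" else "glcm"
  vol <- volume
  whole <- partition$whole; inner <- partition$inner; outer <- partition$outer
  if (subsample) {
    # anchor the 2x pooling blocks at the ROI bounding box so the family
    # is invariant to translating the nodule within the grid
    bb <- mask_bbox(partition$whole)
    vol_c <- crop_bbox(volume, bb)
    ds <- block_downsample2(vol_c, crop_bbox(partition$whole, bb))
    vol <- ds$volume
    whole <- ds$mask
    inner <- block_downsample2(vol_c, crop_bbox(partition$inner, bb))$mask
    outer <- block_downsample2(vol_c, crop_bbox(partition$outer, bb))$mask
    if (sum(whole) < 2L) {
      return(fb_fail(new_feature_block(),
                     paste(prefix, rep(c("whole", "inner", "outer", "delta"),
                                       each = length(GLCM_MEASURES)),
                           GLCM_MEASURES, sep = "."),
                     "too_few_voxels"))
    }
  }
  bw <- glcm_roi_block(vol, whole, bins$glcm_bins, paste0(prefix, ".whole"))
  bi <- glcm_roi_block(vol, inner, bins$glcm_bins, paste0(prefix, ".inner"))
  bo <- glcm_roi_block(vol, outer, bins$glcm_bins, paste0(prefix, ".outer"))
  dn <- paste(prefix, "delta", GLCM_MEASURES, sep = ".")
  bd <- if (isTRUE(attr(bi, "ok")) && isTRUE(attr(bo, "ok"))) {
    fb_add(new_feature_block(),
           setNames(unname(bo$values) - unname(bi$values), dn))
  } else {
    fb_fail(new_feature_block(), dn, "degenerate_matrix")
  }
  fb_concat(bw, bi, bo, bd)
}
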