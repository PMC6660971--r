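# Neighbourhood gray tone difference features (Amadasun-King). Only
# voxels whose complete 26-neighbourhood lies inside the ROI are valid —
# the failure mode that small nodules trigger. Intensity binning is
# shared with the ISZM (default 32 levels, ROI min-max).

NGTDM_NAMES <- paste0("ngtdm.", c("coarseness", "contrast", "busyness",
                                  "complexity", "strength"))
NGTDM_EPS <- 1e-12

#' NGTDM per-level sums and occurrence counts
#'
#' @param volume intensity array.
#' @param roi logical ROI.
#' @param bins number of gray levels.
#' @return list with `s_i` (per-level absolute-difference sums), `n_i`
#'   (per-level valid-voxel counts) and `n_valid`, or `NULL` when no voxel
#'   has a complete in-ROI neighbourhood.
#' @export
ngtdm_matrix <- function(volume, roi, bins = 32) {
  bb <- mask_bbox(roi)
  if (is.null(bb)) return(NULL)
  volume <- crop_bbox(volume, bb)              # valid voxels and their full
  roi <- crop_bbox(roi, bb)                    # neighbourhoods lie in the bbox
  lv <- array(NA_real_, dim(roi))
  lv[roi] <- as.numeric(bin_intensities(volume[roi], bins))
  offs <- neighbor_offsets26()
  nbsum <- array(0, dim(roi))
  nbok <- array(TRUE, dim(roi))
  for (r in seq_len(nrow(offs))) {
    nb <- shift3(lv, -offs[r, ], NA_real_)
    nbok <- nbok & !is.na(nb)
    nb[is.na(nb)] <- 0
    nbsum <- nbsum + nb
  }
  valid <- roi & nbok
  if (!any(valid)) return(NULL)
  av <- nbsum[valid] / 26
  gl <- lv[valid]
  s_i <- vapply(seq_len(bins), function(i) sum(abs(i - av)[gl == i]), numeric(1))
  n_i <- tabulate(as.integer(gl), nbins = bins)
  list(s_i = s_i, n_i = n_i, n_valid = sum(n_i))
}

#' NGTDM features (5 values)
#'
#' Coarseness, contrast, busyness, complexity and strength per the
#' standard formulas, with a 1e-12 guard on zero denominators.
#'
#' @param volume intensity array.
#' @param roi logical ROI.
#' @param bins a [binning_spec()] (uses `iszm_bins`, shared binning).
#' @return A `feature_block` of 5 values.
#' @export
ngtdm_features <- function(volume, roi, bins = binning_spec()) {
  blk <- new_feature_block()
  M <- if (any(roi)) ngtdm_matrix(volume, roi, bins$iszm_bins) else NULL
  if (is.null(M)) return(fb_fail(blk, NGTDM_NAMES, "too_few_voxels"))
  N <- M$n_valid
  p <- M$n_i / N
  s <- M$s_i
  pres <- which(p > 0)
  ngp <- length(pres)
  coarseness <- 1 / (sum(p * s) + NGTDM_EPS)
  if (ngp > 1) {
    ii <- matrix(pres, ngp, ngp)
    jj <- t(ii)
    pij <- outer(p[pres], p[pres])
    contrast <- sum(pij * (ii - jj)^2) / (ngp * (ngp - 1)) * sum(s) / N
    busy_den <- sum(abs(outer(pres * p[pres], pres * p[pres], "-")))
    busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0
    ps <- p[pres] * s[pres]
    num_c <- abs(ii - jj) * (matrix(ps, ngp, ngp) + matrix(ps, ngp, ngp, byrow = TRUE)) /
      (matrix(p[pres], ngp, ngp) + matrix(p[pres], ngp, ngp, byrow = TRUE))
    complexity <- sum(num_c) / N
    strength <- sum((matrix(p[pres], ngp, ngp) +
                       matrix(p[pres], ngp, ngp, byrow = TRUE)) * (ii - jj)^2) /
      (NGTDM_EPS + sum(s))
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  fb_add(blk, setNames(c(coarseness, contrast, busyness, complexity, strength),
                       NGTDM_NAMES))
}
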