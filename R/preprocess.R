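# Resampling and ROI partitioning. Texture families need directional
# voxel-neighbourhood information, so multi-setting comparisons resample
# to a common (coarser) isotropic grid: intensities by trilinear
# interpolation, masks by nearest neighbour.

#' Resample a case to isotropic voxels
#'
#' Down-samples the volume with trilinear interpolation and the mask with
#' nearest-neighbour lookup to an exactly isotropic `(t, t, t)` grid whose
#' physical extent matches the input within one voxel. Up-sampling works
#' but down-sampling small voxels to large ones is the intended use.
#'
#' @param case an [image_case()].
#' @param target_spacing isotropic target spacing in mm (default 2).
#' @return A resampled [image_case()].
#' @export
resample_isotropic <- function(case, target_spacing = 2.0) {
  t <- as.numeric(target_spacing)
  stopifnot(length(t) == 1L, t > 0)
  dm <- dim(case$volume)
  extent <- dm * case$spacing
  out_dim <- pmax(1L, as.integer(round(extent / t)))
  # origin-preserving grid: the centre of the first voxel is fixed, so the
  # mapping reduces to the identity when the native spacing already equals
  # the target
  grids <- lapply(1:3, function(ax) {
    (seq_len(out_dim[ax]) - 1) * t / case$spacing[ax] + 1
  })
  pts <- cbind(
    rep(grids[[1]], times = out_dim[2] * out_dim[3]),
    rep(rep(grids[[2]], each = out_dim[1]), times = out_dim[3]),
    rep(grids[[3]], each = out_dim[1] * out_dim[2]))
  vol <- array(interp3(case$volume, pts), out_dim)
  msk <- array(nearest3(case$mask, pts) > 0, out_dim)
  if (!any(msk))
    stop("empty ROI: nodule smaller than one target voxel after resampling",
         call. = FALSE)
  out <- image_case(case$case_id, vol, msk, rep(t, 3), status = case$status)
  attr(out, "truth") <- attr(case, "truth")
  out
}

#' Partition an ROI into whole, inner, outer and positive sub-regions
#'
#' The inner ROI is obtained by iterative 6-connected binary erosion,
#' stopping at the depth whose retained volume is nearest to 2/3 of the
#' whole ROI (ties broken toward the deeper erosion). The outer ROI is the
#' complement within the whole ROI, and the positive ROI keeps whole-ROI
#' voxels with intensity strictly above 0 HU (the CT water point).
#'
#' @param case an [image_case()].
#' @return list of class `roi_partition` with logical arrays `whole`,
#'   `inner`, `outer`, `positive`, the achieved `inner_ratio` and a
#'   `degenerate` flag (set when one erosion empties the mask, in which case
#'   the inner ROI collapses to the voxel nearest the centroid).
#' @export
partition_roi <- function(case) {
  whole <- case$mask
  n_whole <- sum(whole)
  if (n_whole == 0L) stop("empty ROI", call. = FALSE)
  target <- 2 / 3 * n_whole
  degenerate <- FALSE
  er <- erode6(whole)
  if (sum(er) == 0L) {
    idx <- which(whole, arr.ind = TRUE)
    ctr <- colMeans(idx)
    d2 <- rowSums((idx - matrix(ctr, nrow(idx), 3, byrow = TRUE))^2)
    pick <- idx[which.min(d2), , drop = FALSE]
    inner <- array(FALSE, dim(whole))
    inner[pick] <- TRUE
    degenerate <- TRUE
  } else {
    depths <- list(whole)          # depth 0 = no erosion
    vols <- n_whole
    cur <- er
    while (sum(cur) > 0L) {
      depths[[length(depths) + 1L]] <- cur
      vols <- c(vols, sum(cur))
      cur <- erode6(cur)
    }
    gap <- abs(vols - target)
    best <- max(which(gap == min(gap)))  # tie -> deeper (smaller inner)
    inner <- depths[[best]]
  }
  outer <- whole & !inner
  positive <- whole & (case$volume > 0)
  structure(list(whole = whole, inner = inner, outer = outer,
                 positive = positive,
                 inner_ratio = sum(inner) / n_whole,
                 degenerate = degenerate),
            class = "roi_partition")
}

#' @export
print.roi_partition <- function(x, ...) {
  cat(sprintf("<roi_partition> |whole| = %d, |inner| = %d (%.2f), |outer| = %d, |positive| = %d%s\n",
              sum(x$whole), sum(x$inner), x$inner_ratio, sum(x$outer),
              sum(x$positive), if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
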