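# Margin sharpness by sigmoid fits along surface normals. For each sampled
# surface voxel a line is cast along the (inward-oriented) surface normal
# covering +/- L mm, intensities are sampled at sub-voxel steps with
# trilinear interpolation, and s(t) = a + b / (1 + exp(-(t - c) / w)) is
# fitted by damped (Levenberg-Marquardt) least squares with deterministic
# initialization. The margin slope of a line is b / (4w), the maximum
# derivative of the fitted sigmoid; per half-length the family reports the
# mean and SD of the slope over lines.

SIGMOID_HALF_LENGTHS <- c(3, 5, 7)

sigmoid_names <- function(half_lengths = SIGMOID_HALF_LENGTHS) {
  as.vector(t(outer(paste0("sigmoid.l", half_lengths),
                    c("slope_mean", "slope_sd"), paste, sep = ".")))
}

# One 4-parameter LM fit; returns c(a, b, c, w) or NULL on failure.
fit_sigmoid_line <- function(t, y, maxit = 200, tol = 1e-8) {
  rng <- max(y) - min(y)
  if (rng < 1e-6) return(NULL)                 # flat line: degenerate fit
  th <- c(a = min(y), b = rng, c = 0, w = 1)
  model <- function(th) th[1] + th[2] / (1 + exp(-(t - th[3]) / th[4]))
  r <- y - model(th)
  sse <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  for (it in seq_len(maxit)) {
    z <- (t - th[3]) / th[4]
    sig <- 1 / (1 + exp(-z))
    dsig <- sig * (1 - sig)
    J <- cbind(1, sig, -th[2] * dsig / th[4], -th[2] * dsig * z / th[4])
    g <- crossprod(J, r)
    H <- crossprod(J)
    step <- tryCatch(solve(H + lambda * diag(diag(H) + 1e-12)), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    delta <- as.vector(step %*% g)
    th_new <- th + delta
    th_new[4] <- max(th_new[4], 1e-3)          # keep the width positive
    r_new <- y - model(th_new)
    sse_new <- sum(r_new^2)
    if (!is.finite(sse_new)) return(NULL)
    if (sse_new < sse) {
      improved <- sse - sse_new
      th <- th_new; r <- r_new; sse <- sse_new
      lambda <- max(lambda / 10, 1e-12)
      if (improved < tol * (sse + tol)) { converged <- TRUE; break }
    } else {
      lambda <- lambda * 10
      if (lambda > 1e10) break
    }
  }
  if (!converged && it == maxit) return(NULL)
  if (!converged && lambda > 1e10 && sse > tol) {
    # stalled without entering the convergence basin
    if (sum(r^2) / length(r) > 1e-4 * stats::var(y)) return(NULL)
  }
  th
}

# Inward-pointing unit surface normals (mm space) at given surface voxels,
# from the gradient of the Gaussian-smoothed (sigma = 1 voxel) mask.
surface_normals <- function(mask, spacing, surf_idx) {
  sm <- gauss_smooth3(array(as.numeric(mask), dim(mask)), 1)
  grad <- vector("list", 3)
  for (ax in 1:3) {
    d <- c(0L, 0L, 0L); d[ax] <- 1L
    grad[[ax]] <- (shift3(sm, -d, 0) - shift3(sm, d, 0)) / (2 * spacing[ax])
  }
  G <- cbind(grad[[1]][surf_idx], grad[[2]][surf_idx], grad[[3]][surf_idx])
  nrm <- sqrt(rowSums(G^2))
  ok <- nrm > 1e-9
  G[ok, ] <- G[ok, , drop = FALSE] / nrm[ok]
  list(normals = G, ok = ok)                   # inward = +gradient
}

#' Sigmoid margin features (6 values)
#'
#' @param volume intensity array (HU).
#' @param mask logical nodule mask.
#' @param spacing voxel spacing in mm.
#' @param half_lengths line half-lengths in mm (default 3, 5, 7).
#' @param step sampling step along the line in mm.
#' @param max_lines deterministic cap on the number of surface voxels
#'   sampled (even stride over the surface); keeps fine-spacing grids
#'   tractable without changing the line-level statistics.
#' @return A `feature_block` with `slope_mean` and `slope_sd` per length.
#' @export
sigmoid_margin_features <- function(volume, mask, spacing,
                                    half_lengths = SIGMOID_HALF_LENGTHS,
                                    step = 0.5, max_lines = 120) {
  nms <- sigmoid_names(half_lengths)
  blk <- new_feature_block()
  if (sum(mask) < 2L) return(fb_fail(blk, nms, "too_few_voxels"))
  surf <- which(mask & !erode6(mask))
  if (length(surf) > max_lines) {
    surf <- surf[unique(round(seq(1, length(surf), length.out = max_lines)))]
  }
  sn <- surface_normals(mask, spacing, surf)
  keep <- sn$ok
  surf <- surf[keep]
  normals <- sn$normals[keep, , drop = FALSE]
  if (length(surf) < 1L) return(fb_fail(blk, nms, "too_few_voxels"))
  origin <- arrayInd(surf, dim(mask))          # voxel indices of line origins
  for (li in seq_along(half_lengths)) {
    L <- half_lengths[li]
    tgrid <- seq(-L, L, by = step)             # t > 0 points inward
    slopes <- rep(NA_real_, length(surf))
    for (s in seq_along(surf)) {
      dirs <- normals[s, ]                     # inward in mm space
      pts <- matrix(origin[s, ], length(tgrid), 3, byrow = TRUE) +
        outer(tgrid, dirs / spacing)           # fractional voxel indices
      y <- interp3(volume, pts)
      th <- fit_sigmoid_line(tgrid, y)
      if (!is.null(th)) slopes[s] <- th[2] / (4 * th[4])
    }
    ok <- !is.na(slopes)
    if (mean(ok) <= 0.5) {
      blk <- fb_fail(blk, nms[c(2 * li - 1, 2 * li)], "fit_nonconvergence")
    } else {
      blk <- fb_add(blk, setNames(
        c(mean(slopes[ok]), if (sum(ok) > 1) sd(slopes[ok]) else 0),
        nms[c(2 * li - 1, 2 * li)]))
    }
  }
  blk
}
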