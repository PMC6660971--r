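# Fractal descriptors of the mask and of the masked intensity surface:
# box-counting dimension over dyadic box sizes, gliding-box lacunarity,
# and the blanket-method fractal signature of the intensity surface.

FRACTAL_LAC_R <- 2:8
FRACTAL_FSD_E <- 2:8

fractal_names <- function() {
  c("fractal.boxdim",
    paste0("fractal.lacunarity.r", FRACTAL_LAC_R),
    paste0("fractal.fsd.e", FRACTAL_FSD_E))
}

# Box-counting N(s) on the mask bounding box, grid anchored at the box
# corner; boxes may extend past thin axes.
box_count <- function(m, s) {
  dm <- dim(m)
  nb <- ceiling(dm / s)
  idx <- which(m, arr.ind = TRUE)
  bi <- ceiling(idx / matrix(s, nrow(idx), 3, byrow = TRUE))
  length(unique(bi[, 1] + (bi[, 2] - 1) * nb[1] +
                   (bi[, 3] - 1) * nb[1] * nb[2]))
}

box_counting_dimension <- function(m) {
  sizes <- c(1, 2, 4, 8, 16)
  sizes <- sizes[sizes <= max(dim(m))]
  if (length(sizes) < 3L) return(NA_real_)
  N <- vapply(sizes, function(s) box_count(m, s), numeric(1))
  fit <- stats::lm.fit(cbind(1, log(sizes)), log(N))
  -fit$coefficients[2]
}

gliding_lacunarity <- function(m, r) {
  M <- boxsum3(m * 1, r)
  if (is.null(M)) return(NA_real_)
  mu <- mean(M)
  if (mu == 0) return(NA_real_)
  mean(M^2) / mu^2                  # = var/mean^2 + 1 (population moments)
}

# Blanket surfaces of the intensity field restricted to the mask.
# u_eps grows by 1 per step or to the max 6-neighbour (within mask);
# b_eps symmetrically shrinks. A(eps) = sum(u - b) / (2 eps).
blanket_signature <- function(volume, mask, eps_max = max(FRACTAL_FSD_E)) {
  bb <- mask_bbox(mask)
  m <- crop_bbox(mask, bb, pad = 1L)
  v <- crop_bbox(volume, bb, pad = 1L)
  u <- v; b <- v
  u[!m] <- -Inf; b[!m] <- Inf
  nb_max <- function(a) {
    out <- a
    for (ax in 1:3) {
      d <- c(0L, 0L, 0L); d[ax] <- 1L
      out <- pmax(out, shift3(a, d, -Inf), shift3(a, -d, -Inf))
    }
    out
  }
  nb_min <- function(a) {
    out <- a
    for (ax in 1:3) {
      d <- c(0L, 0L, 0L); d[ax] <- 1L
      out <- pmin(out, shift3(a, d, Inf), shift3(a, -d, Inf))
    }
    out
  }
  A <- numeric(eps_max)
  for (eps in seq_len(eps_max)) {
    u_new <- pmax(u + 1, nb_max(u)); u_new[!m] <- -Inf
    b_new <- pmin(b - 1, nb_min(b)); b_new[!m] <- Inf
    u <- u_new; b <- b_new
    A[eps] <- sum(u[m] - b[m]) / (2 * eps)
  }
  A
}

#' Fractal features (15 values)
#'
#' Box-counting fractal dimension of the mask (least-squares slope of
#' log N(s) vs log s over dyadic sizes), gliding-box lacunarity at box
#' sizes 2..8, and the blanket-method fractal signature S(eps) of the
#' masked intensity surface at eps = 2..8.
#'
#' @param mask logical 3D array.
#' @param volume intensity array (HU).
#' @return A `feature_block` of 15 values.
#' @export
fractal_features <- function(mask, volume) {
  nms <- fractal_names()
  blk <- new_feature_block()
  bb <- mask_bbox(mask)
  if (is.null(bb)) return(fb_fail(blk, nms, "empty_roi"))
  ext <- bb$hi - bb$lo + 1L
  if (max(ext) < 4L) return(fb_fail(blk, nms, "too_few_voxels"))
  m <- crop_bbox(mask, bb)
  bd <- box_counting_dimension(m)
  blk <- if (is.na(bd)) fb_fail(blk, nms[1], "too_few_voxels") else
    fb_add(blk, setNames(bd, nms[1]))
  lac <- vapply(FRACTAL_LAC_R, function(r) gliding_lacunarity(m, r), numeric(1))
  lac_names <- paste0("fractal.lacunarity.r", FRACTAL_LAC_R)
  for (i in seq_along(lac)) {
    blk <- if (is.na(lac[i])) fb_fail(blk, lac_names[i], "too_few_voxels") else
      fb_add(blk, setNames(lac[i], lac_names[i]))
  }
  A <- blanket_signature(volume, mask)
  S <- 2 - diff(log(A)) / diff(log(seq_along(A)))   # S(eps) for eps = 2..eps_max
  fsd_names <- paste0("fractal.fsd.e", FRACTAL_FSD_E)
  S <- S[FRACTAL_FSD_E - 1L]
  for (i in seq_along(S)) {
    blk <- if (!is.finite(S[i])) fb_fail(blk, fsd_names[i], "degenerate_matrix") else
      fb_add(blk, setNames(S[i], fsd_names[i]))
  }
  blk
}
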