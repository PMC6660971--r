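# 3D and 2D shape features. Surface area comes from a marching-tetrahedra
# mesh of the Gaussian-smoothed mask indicator at iso-level 0.5 (falling
# back to the raw binary indicator when smoothing removes the crossing,
# e.g. for very small masks); the smoothing suppresses the staircase bias
# a binary digitization imposes on curved surfaces.

SHAPE3D_NAMES <- c("volume", "surface_area", "surface_volume_ratio",
                   "compactness", "sphericity", "spherical_disproportion",
                   "max_diameter_3d", "equivalent_diameter",
                   "elongation", "flatness")
SHAPE2D_NAMES <- c("area_2d", "perimeter_2d", "circularity_2d")

tri_area_rows <- function(p1, p2, p3) {
  u <- p2 - p1
  v <- p3 - p1
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Surface area contribution of one tetrahedron family, vectorized over
# cells. P is a list of four n x 3 corner-coordinate matrices, V an n x 4
# value matrix.
tet_area_vec <- function(P, V, level) {
  above <- V > level
  pattern <- above[, 1] + 2L * above[, 2] + 4L * above[, 3] + 8L * above[, 4]
  interp <- function(rows, i, j) {
    t <- (level - V[rows, i]) / (V[rows, j] - V[rows, i])
    P[[i]][rows, , drop = FALSE] +
      t * (P[[j]][rows, , drop = FALSE] - P[[i]][rows, , drop = FALSE])
  }
  total <- 0
  for (pat in 1:14) {
    rows <- which(pattern == pat)
    if (!length(rows)) next
    bits <- which(bitwAnd(pat, c(1L, 2L, 4L, 8L)) > 0L)
    if (length(bits) %in% c(1L, 3L)) {
      s <- if (length(bits) == 1L) bits else setdiff(1:4, bits)
      o <- setdiff(1:4, s)
      total <- total + sum(tri_area_rows(interp(rows, s, o[1]),
                                         interp(rows, s, o[2]),
                                         interp(rows, s, o[3])))
    } else {                       # 2 above, 2 below
      a <- bits
      b <- setdiff(1:4, bits)
      p11 <- interp(rows, a[1], b[1]); p12 <- interp(rows, a[1], b[2])
      p21 <- interp(rows, a[2], b[1]); p22 <- interp(rows, a[2], b[2])
      total <- total + sum(tri_area_rows(p11, p12, p22)) +
        sum(tri_area_rows(p11, p22, p21))
    }
  }
  total
}

# Six-tetrahedra cube decomposition sharing the (0,0,0)-(1,1,1) diagonal.
TET_CORNERS <- matrix(c(1, 2, 4, 8,
                        1, 4, 3, 8,
                        1, 3, 7, 8,
                        1, 7, 5, 8,
                        1, 5, 6, 8,
                        1, 6, 2, 8), ncol = 4, byrow = TRUE)
CUBE_OFFSETS <- as.matrix(expand.grid(0:1, 0:1, 0:1))[c(1, 2, 3, 4, 5, 6, 7, 8), ]
# corner order: 1 (0,0,0), 2 (1,0,0), 3 (0,1,0), 4 (1,1,0),
#               5 (0,0,1), 6 (1,0,1), 7 (0,1,1), 8 (1,1,1)

#' Mesh surface area of a binary mask (marching tetrahedra)
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing in mm.
#' @param smooth_sigma Gaussian pre-smoothing of the indicator in voxels
#'   (0 = mesh the raw binary field).
#' @return surface area in mm^2.
#' @export
mesh_surface_area <- function(mask, spacing, smooth_sigma = 0.53) {
  bb <- mask_bbox(mask)
  if (is.null(bb)) stop("empty ROI", call. = FALSE)
  pad <- max(2L, ceiling(3 * smooth_sigma) + 1L)
  m <- crop_bbox(mask, bb)
  dm <- dim(m)
  f0 <- array(0, dm + 2L * pad)
  f0[pad + seq_len(dm[1]), pad + seq_len(dm[2]), pad + seq_len(dm[3])] <- m
  f <- if (smooth_sigma > 0) gauss_smooth3(f0, smooth_sigma) else f0
  if (max(f) <= 0.5) f <- f0       # smoothing erased a tiny mask
  level <- 0.5
  dmf <- dim(f)
  above <- f > level
  # cells with mixed corners only
  acc <- array(0L, dmf - 1L)
  for (r in seq_len(8)) {
    o <- CUBE_OFFSETS[r, ]
    acc <- acc + above[(1 + o[1]):(dmf[1] - 1 + o[1]),
                       (1 + o[2]):(dmf[2] - 1 + o[2]),
                       (1 + o[3]):(dmf[3] - 1 + o[3])]
  }
  cells <- which(acc > 0L & acc < 8L, arr.ind = TRUE)
  if (nrow(cells) == 0L) return(0)
  V8 <- matrix(0, nrow(cells), 8)
  C8 <- vector("list", 8)
  for (r in seq_len(8)) {
    o <- CUBE_OFFSETS[r, ]
    V8[, r] <- f[cbind(cells[, 1] + o[1], cells[, 2] + o[2], cells[, 3] + o[3])]
    C8[[r]] <- sweep(cells + matrix(o, nrow(cells), 3, byrow = TRUE), 2,
                     spacing, "*")
  }
  area <- 0
  for (tt in seq_len(nrow(TET_CORNERS))) {
    ids <- TET_CORNERS[tt, ]
    area <- area + tet_area_vec(C8[ids], V8[, ids, drop = FALSE], level)
  }
  area
}

max_diameter_3d <- function(mask, spacing) {
  surf <- mask & !erode6(mask)
  idx <- which(surf, arr.ind = TRUE)
  if (nrow(idx) < 2L) return(0)
  pts <- sweep(idx, 2, spacing, "*")
  best <- 0
  chunk <- 400L
  for (s in seq(1L, nrow(pts), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pts))
    block <- pts[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(pts^2), "+") -
      2 * block %*% t(pts)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' 3D shape features (10 values)
#'
#' Volume, mesh surface area, surface-to-volume ratio, compactness
#' (V / (sqrt(pi) A^(3/2))), sphericity (pi^(1/3) (6V)^(2/3) / A), spherical
#' disproportion (1 / sphericity), maximum 3D diameter (largest pairwise
#' distance between surface voxels), equivalent spherical diameter, and
#' PCA-based elongation and flatness.
#'
#' @param mask logical 3D array (non-empty).
#' @param spacing voxel spacing in mm.
#' @return named numeric vector of 10 values.
#' @export
shape3d_features <- function(mask, spacing) {
  n <- sum(mask)
  if (n == 0L) stop("empty ROI", call. = FALSE)
  voxvol <- prod(spacing)
  V <- n * voxvol
  A <- mesh_surface_area(mask, spacing)
  sph <- pi^(1 / 3) * (6 * V)^(2 / 3) / A
  idx <- which(mask, arr.ind = TRUE)
  pts <- sweep(idx, 2, spacing, "*")
  if (n >= 2L) {
    ev <- sort(eigen(stats::cov(pts), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
    elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
    flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  } else {
    elong <- 1; flat <- 1
  }
  setNames(c(V, A, A / V, V / (sqrt(pi) * A^1.5), sph, 1 / sph,
             max_diameter_3d(mask, spacing), (6 * V / pi)^(1 / 3),
             elong, flat),
           SHAPE3D_NAMES)
}

# Marching-squares perimeter of a 2D logical slice (smoothed indicator,
# midpoint fallback as in the 3D case).
marching_perimeter <- function(slice, spacing2, smooth_sigma = 0.6) {
  dm <- dim(slice)
  pad <- max(4L, ceiling(3 * smooth_sigma) + 1L)
  f0 <- matrix(0, dm[1] + 2L * pad, dm[2] + 2L * pad)
  f0[pad + seq_len(dm[1]), pad + seq_len(dm[2])] <- slice
  # 2D separable Gaussian smoothing via the 3D helper on a 1-thick array
  f <- gauss_smooth3(array(f0, c(dim(f0), 1L)),
                     c(smooth_sigma, smooth_sigma, 0))[, , 1]
  if (max(f) <= 0.5) f <- f0
  level <- 0.5
  dmf <- dim(f)
  v1 <- f[-dmf[1], -dmf[2]]; v2 <- f[-1, -dmf[2]]
  v3 <- f[-dmf[1], -1];      v4 <- f[-1, -1]
  # corners: 1 (0,0), 2 (1,0), 3 (0,1), 4 (1,1)
  corner_pos <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  V <- cbind(as.vector(v1), as.vector(v2), as.vector(v3), as.vector(v4))
  above <- V > level
  pattern <- above[, 1] + 2L * above[, 2] + 4L * above[, 3] + 8L * above[, 4]
  cells <- which(pattern > 0L & pattern < 15L)
  if (!length(cells)) return(0)
  ci <- arrayInd(cells, dmf - 1L)
  # edges between corner pairs: (1,2) bottom, (1,3) left, (2,4) right, (3,4) top
  edge_pt <- function(rows, i, j) {
    t <- (level - V[rows, i]) / (V[rows, j] - V[rows, i])
    p0 <- matrix(corner_pos[[i]], length(rows), 2, byrow = TRUE)
    p1 <- matrix(corner_pos[[j]], length(rows), 2, byrow = TRUE)
    (ci[match(rows, cells), , drop = FALSE] + p0 + t * (p1 - p0)) *
      matrix(spacing2, length(rows), 2, byrow = TRUE)
  }
  seg_len <- function(a, b) sum(sqrt(rowSums((a - b)^2)))
  total <- 0
  # segment table per marching-squares pattern (ambiguous saddles split)
  segs <- list(
    `1` = list(c(1, 2, 1, 3)), `2` = list(c(1, 2, 2, 4)),
    `3` = list(c(1, 3, 2, 4)), `4` = list(c(1, 3, 3, 4)),
    `5` = list(c(1, 2, 3, 4)), `6` = list(c(1, 2, 1, 3), c(2, 4, 3, 4)),
    `7` = list(c(2, 4, 3, 4)), `8` = list(c(2, 4, 3, 4)),
    `9` = list(c(1, 2, 2, 4), c(1, 3, 3, 4)), `10` = list(c(1, 2, 3, 4)),
    `11` = list(c(1, 3, 3, 4)), `12` = list(c(1, 3, 2, 4)),
    `13` = list(c(1, 2, 2, 4)), `14` = list(c(1, 2, 1, 3)))
  for (pat in 1:14) {
    rows <- cells[pattern[cells] == pat]
    if (!length(rows)) next
    for (sg in segs[[as.character(pat)]]) {
      total <- total + seg_len(edge_pt(rows, sg[1], sg[2]),
                               edge_pt(rows, sg[3], sg[4]))
    }
  }
  total
}

#' 2D shape features on the largest axial slice (3 values)
#'
#' Area, marching-squares perimeter and circularity (4 pi A / P^2) on the
#' axial slice of maximal cross-sectional area (ties go to the lower slice
#' index).
#'
#' @inheritParams shape3d_features
#' @return named numeric vector of 3 values.
#' @export
shape2d_features <- function(mask, spacing) {
  if (!any(mask)) stop("empty ROI", call. = FALSE)
  counts <- apply(mask, 3, sum)
  k <- which.max(counts)            # which.max takes the first (lower) tie
  slice <- mask[, , k]
  a <- sum(slice) * spacing[1] * spacing[2]
  p <- marching_perimeter(slice, spacing[1:2])
  circ <- if (p > 0) 4 * pi * a / p^2 else NA_real_
  setNames(c(a, p, circ), SHAPE2D_NAMES)
}
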