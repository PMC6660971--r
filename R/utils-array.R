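# Low-level 3D array helpers shared by the synthetic generator, the
# preprocessor and the feature families. All arrays are indexed [i, j, k]
# with axis 3 as the slice axis; spacing vectors are in mm per axis.

# Shift a 3D array by integer offsets, filling vacated voxels with `fill`.
shift3 <- function(a, d, fill = 0L) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- vector("list", 3L)
  dst <- vector("list", 3L)
  for (ax in 1:3) {
    n <- dm[ax]
    if (d[ax] >= n || d[ax] <= -n) return(out)
    if (d[ax] >= 0) {
      src[[ax]] <- seq_len(n - d[ax])
      dst[[ax]] <- seq_len(n - d[ax]) + d[ax]
    } else {
      src[[ax]] <- seq_len(n + d[ax]) - d[ax]
      dst[[ax]] <- seq_len(n + d[ax])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# 6-connected binary erosion (face-adjacent structuring element).
erode6 <- function(mask) {
  m <- mask
  for (ax in 1:3) {
    d <- c(0L, 0L, 0L)
    d[ax] <- 1L
    m <- m & shift3(mask, d, FALSE) & shift3(mask, -d, FALSE)
  }
  m
}

# The 26 neighbor offsets (Chebyshev distance 1) and the 13 unique
# co-occurrence directions (first nonzero component positive).
neighbor_offsets26 <- function() {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

glcm_directions13 <- function() {
  g <- neighbor_offsets26()
  keep <- apply(g, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  g[keep, , drop = FALSE]
}

# Bounding box of a logical mask; returns NULL when empty.
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  list(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
}

crop_bbox <- function(a, bb, pad = 0L) {
  dm <- dim(a)
  lo <- pmax(bb$lo - pad, 1L)
  hi <- pmin(bb$hi + pad, dm)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
}

# Trilinear interpolation of `vol` at fractional 1-based voxel indices
# (n x 3 matrix). Out-of-grid positions are clamped to the border.
interp3 <- function(vol, pts) {
  dm <- dim(vol)
  x <- pmin(pmax(pts[, 1], 1), dm[1])
  y <- pmin(pmax(pts[, 2], 1), dm[2])
  z <- pmin(pmax(pts[, 3], 1), dm[3])
  x0 <- pmin(floor(x), dm[1] - 1L); x0 <- pmax(x0, 1L)
  y0 <- pmin(floor(y), dm[2] - 1L); y0 <- pmax(y0, 1L)
  z0 <- pmin(floor(z), dm[3] - 1L); z0 <- pmax(z0, 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  if (dm[1] == 1L) { x0 <- rep(1L, length(x)); fx <- 0 }
  if (dm[2] == 1L) { y0 <- rep(1L, length(y)); fy <- 0 }
  if (dm[3] == 1L) { z0 <- rep(1L, length(z)); fz <- 0 }
  lin <- function(i, j, k) vol[cbind(i, j, k)]
  x1 <- pmin(x0 + 1L, dm[1]); y1 <- pmin(y0 + 1L, dm[2]); z1 <- pmin(z0 + 1L, dm[3])
  c000 <- lin(x0, y0, z0); c100 <- lin(x1, y0, z0)
  c010 <- lin(x0, y1, z0); c110 <- lin(x1, y1, z0)
  c001 <- lin(x0, y0, z1); c101 <- lin(x1, y0, z1)
  c011 <- lin(x0, y1, z1); c111 <- lin(x1, y1, z1)
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

# Nearest-neighbor lookup at fractional indices (for binary masks).
nearest3 <- function(vol, pts) {
  dm <- dim(vol)
  i <- pmin(pmax(round(pts[, 1]), 1), dm[1])
  j <- pmin(pmax(round(pts[, 2]), 1), dm[2])
  k <- pmin(pmax(round(pts[, 3]), 1), dm[3])
  vol[cbind(i, j, k)]
}

# Separable convolution with a symmetric 1D kernel along each axis,
# replicating the border. Kernel lengths are odd.
sepconv3 <- function(a, kernels) {
  dm <- dim(a)
  out <- a
  for (ax in 1:3) {
    k <- kernels[[ax]]
    if (length(k) == 1L) { out <- out * k; next }
    r <- (length(k) - 1L) %/% 2L
    n <- dm[ax]
    idx <- outer(seq_len(n), -r:r, "+")
    idx <- pmin(pmax(idx, 1L), n)           # replicate border
    K <- matrix(0, n, n)
    for (m in seq_along(k)) {
      K[cbind(seq_len(n), idx[, m])] <- K[cbind(seq_len(n), idx[, m])] + k[m]
    }
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(out, perm)
    dp <- dim(ap)
    ap <- K %*% matrix(ap, nrow = dp[1])
    dim(ap) <- dp
    out <- aperm(ap, order(perm))
  }
  out
}

gauss_kernel1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  if (sigma <= 0) return(1)
  x <- -radius:radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian smoothing with per-axis sigma in voxel units.
gauss_smooth3 <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  sepconv3(a, lapply(sigma_vox, gauss_kernel1d))
}

# Replicate-pad a 3D array by `w` voxels per axis (vector of 3).
pad_replicate3 <- function(a, w) {
  w <- rep_len(w, 3L)
  dm <- dim(a)
  ix <- pmin(pmax(seq_len(dm[1] + 2 * w[1]) - w[1], 1L), dm[1])
  iy <- pmin(pmax(seq_len(dm[2] + 2 * w[2]) - w[2], 1L), dm[2])
  iz <- pmin(pmax(seq_len(dm[3] + 2 * w[3]) - w[3], 1L), dm[3])
  a[ix, iy, iz, drop = FALSE]
}

# Circular 3D convolution via FFT with the kernel centered at the origin.
# Caller is responsible for padding; output has the same dims as `a`.
fftconv3 <- function(a, kernel) {
  dm <- dim(a)
  dk <- dim(kernel)
  stopifnot(all(dk <= dm))
  kc <- array(0, dm)
  kc[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kernel
  ctr <- (dk + 1L) %/% 2L
  for (ax in 1:3) {
    perm <- seq_len(3)
    ord <- c((ctr[ax]):dm[ax], seq_len(ctr[ax] - 1L))
    kc <- switch(ax,
      kc[ord, , , drop = FALSE],
      kc[, ord, , drop = FALSE],
      kc[, , ord, drop = FALSE])
  }
  Re(fft(fft(a) * fft(kc), inverse = TRUE)) / prod(dm)
}

# Moving-window sums over r x r x r boxes fully inside the array
# (summed-area-table based). Returns an array of valid window sums.
boxsum3 <- function(a, r) {
  dm <- dim(a)
  if (any(dm < r)) return(NULL)
  s <- a
  for (ax in 1:3) {
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    sp <- aperm(s, perm)
    dp <- dim(sp)
    m <- matrix(sp, nrow = dp[1])
    cs <- apply(m, 2, cumsum)
    n_out <- dp[1] - r + 1L
    win <- cs[r:dp[1], , drop = FALSE]
    if (n_out > 1L) {
      win[2:n_out, ] <- win[2:n_out, , drop = FALSE] -
        cs[1:(n_out - 1L), , drop = FALSE]
    }
    dim(win) <- c(n_out, dp[2], dp[3])
    s <- aperm(win, order(perm))
  }
  s
}

# 26-connected component labelling of a logical mask (BFS on linear
# indices over a zero-padded copy to avoid wrap-around).
label_components26 <- function(mask) {
  dm <- dim(mask)
  p <- array(FALSE, dm + 2L)
  p[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)] <- mask
  dmp <- dim(p)
  offs <- neighbor_offsets26()
  lin_offs <- offs[, 1] + offs[, 2] * dmp[1] + offs[, 3] * dmp[1] * dmp[2]
  labels <- integer(length(p))
  todo <- which(p)
  lab <- 0L
  remaining <- logical(length(p))
  remaining[todo] <- TRUE
  for (seed in todo) {
    if (!remaining[seed]) next
    lab <- lab + 1L
    frontier <- seed
    remaining[seed] <- FALSE
    labels[seed] <- lab
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, lin_offs, "+")))
      nb <- nb[nb >= 1L & nb <= length(p)]
      nb <- nb[remaining[nb]]
      if (length(nb)) {
        labels[nb] <- lab
        remaining[nb] <- FALSE
      }
      frontier <- nb
    }
  }
  out <- array(labels, dmp)[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)]
  dim(out) <- dm
  list(labels = out, n = lab)
}

# Equal-width binning of intensities over [lo, hi] into `bins` levels.
# Values exactly at hi land in the top bin; constant input maps to bin 1.
bin_intensities <- function(x, bins, lo = min(x), hi = max(x)) {
  if (hi <= lo) return(rep(1L, length(x)))
  b <- floor((x - lo) / (hi - lo) * bins) + 1L
  pmin(pmax(b, 1L), as.integer(bins))
}
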