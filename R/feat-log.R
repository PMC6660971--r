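# Multiscale Laplacian-of-Gaussian response statistics. Sigma is in voxel
# units (0.5 to 3.5 in 0.5 steps); the volume is replicate-padded, FFT
# convolved with the analytic 3D LoG kernel at each scale, and 9 in-mask
# statistics are taken per scale. Response entropy/uniformity use a
# 256-bin histogram over the response min-max.

LOG_SIGMAS <- seq(0.5, 3.5, by = 0.5)
LOG_STATS <- c("mean", "sd", "skewness", "kurtosis", "min", "max",
               "energy", "entropy", "uniformity")
LOG_RESPONSE_BINS <- 256L

log_names <- function() {
  as.vector(t(outer(sprintf("log.s%.1f", LOG_SIGMAS), LOG_STATS,
                    paste, sep = ".")))
}

log_kernel3 <- function(sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  x <- -r:r
  g <- expand.grid(x = x, y = x, z = x)
  r2 <- g$x^2 + g$y^2 + g$z^2
  k <- (r2 / sigma^4 - 3 / sigma^2) * exp(-r2 / (2 * sigma^2))
  k <- k - mean(k)                  # zero DC response
  array(k, c(length(x), length(x), length(x)))
}

log_response_stats <- function(resp) {
  m <- mean(resp)
  cx <- resp - m
  m2 <- mean(cx^2)
  skew <- if (m2 > 0) mean(cx^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean(cx^4) / m2^2 else 0
  rng <- max(resp) - min(resp)
  if (m2 > 0 && rng > 1e-9 * max(1, max(abs(resp)))) {
    b <- bin_intensities(resp, LOG_RESPONSE_BINS)
    p <- tabulate(b, nbins = LOG_RESPONSE_BINS) / length(resp)
    ent <- entropy_bits(p)
    unif <- sum(p^2)
  } else { ent <- 0; unif <- 1 }
  setNames(c(m, sqrt(m2 * length(resp) / max(1, length(resp) - 1)),
             skew, kurt, min(resp), max(resp), sum(resp^2), ent, unif),
           LOG_STATS)
}

#' Laplacian-of-Gaussian filter features (63 values)
#'
#' @param volume intensity array (HU).
#' @param mask logical nodule mask.
#' @param sigmas filter scales in voxels.
#' @return A `feature_block` of 9 statistics x 7 scales.
#' @export
log_filter_features <- function(volume, mask, sigmas = LOG_SIGMAS) {
  blk <- new_feature_block()
  if (!any(mask)) return(fb_fail(blk, log_names(), "empty_roi"))
  rmax <- max(1L, ceiling(3.5 * max(sigmas)))
  padded <- pad_replicate3(volume, rmax)
  Fv <- fft(padded)
  dm <- dim(padded)
  for (si in seq_along(sigmas)) {
    k <- log_kernel3(sigmas[si])
    dk <- dim(k)
    kc <- array(0, dm)
    kc[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k
    ctr <- (dk + 1L) %/% 2L
    for (ax in 1:3) {
      ord <- c(ctr[ax]:dm[ax], seq_len(ctr[ax] - 1L))
      kc <- switch(ax, kc[ord, , , drop = FALSE],
                   kc[, ord, , drop = FALSE], kc[, , ord, drop = FALSE])
    }
    conv <- Re(fft(Fv * fft(kc), inverse = TRUE)) / prod(dm)
    resp <- conv[rmax + seq_len(dim(volume)[1]),
                 rmax + seq_len(dim(volume)[2]),
                 rmax + seq_len(dim(volume)[3])][mask]
    stats <- log_response_stats(resp)
    names(stats) <- sprintf("log.s%.1f.%s", sigmas[si], LOG_STATS)
    blk <- fb_add(blk, stats)
  }
  blk
}
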