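# Shared fixtures and independent brute-force oracles. Expensive objects
# are memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

make_sphere_case <- function(d, spacing, noise_sd = 0, margin_width = 0,
                             texture_amplitude = 0, seed = 1,
                             grid_margin = 6, ...) {
  generate_case(nodule_spec(d, margin_width = margin_width,
                            texture_amplitude = texture_amplitude, ...),
                spacing, noise_sd = noise_sd, seed = seed,
                grid_margin = grid_margin)
}

# Large, well-behaved textured nodule used by several tests.
large_nodule <- function() {
  fixture("large_nodule", {
    generate_case(nodule_spec(18, margin_width = 1.5, texture_amplitude = 40),
                  c(1, 1, 1), noise_sd = 15, seed = 42, case_id = "big")
  })
}

# O(n * 26) double-loop GLCM oracle, independent of the shift-based path.
glcm_bruteforce <- function(volume, roi, bins) {
  lv <- array(NA_integer_, dim(roi))
  lv[roi] <- radrep:::bin_intensities(volume[roi], bins)
  dm <- dim(roi)
  offs <- radrep:::neighbor_offsets26()
  cnt <- matrix(0, bins, bins)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (is.na(lv[i, j, k])) next
    for (r in seq_len(nrow(offs))) {
      ni <- i + offs[r, 1]; nj <- j + offs[r, 2]; nk <- k + offs[r, 3]
      if (ni < 1 || ni > dm[1] || nj < 1 || nj > dm[2] ||
          nk < 1 || nk > dm[3]) next
      if (is.na(lv[ni, nj, nk])) next
      cnt[lv[i, j, k], lv[ni, nj, nk]] <- cnt[lv[i, j, k], lv[ni, nj, nk]] + 1
    }
  }
  if (sum(cnt) == 0) return(NULL)
  cnt / sum(cnt)
}

# Brute-force NGTDM oracle: explicit loop over voxels with a complete
# 26-neighbourhood.
ngtdm_bruteforce <- function(volume, roi, bins) {
  lv <- array(NA_real_, dim(roi))
  lv[roi] <- as.numeric(radrep:::bin_intensities(volume[roi], bins))
  dm <- dim(roi)
  offs <- radrep:::neighbor_offsets26()
  s_i <- numeric(bins); n_i <- integer(bins)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (is.na(lv[i, j, k])) next
    nb <- numeric(0); complete <- TRUE
    for (r in seq_len(nrow(offs))) {
      ni <- i + offs[r, 1]; nj <- j + offs[r, 2]; nk <- k + offs[r, 3]
      if (ni < 1 || ni > dm[1] || nj < 1 || nj > dm[2] ||
          nk < 1 || nk > dm[3] || is.na(lv[ni, nj, nk])) {
        complete <- FALSE
        break
      }
      nb <- c(nb, lv[ni, nj, nk])
    }
    if (!complete) next
    g <- as.integer(lv[i, j, k])
    s_i[g] <- s_i[g] + abs(g - mean(nb))
    n_i[g] <- n_i[g] + 1L
  }
  if (sum(n_i) == 0) return(NULL)
  list(s_i = s_i, n_i = n_i, n_valid = sum(n_i))
}

# Recursive flood-fill zone enumeration oracle for the ISZM.
iszm_bruteforce_sizes <- function(volume, roi, bins) {
  lv <- array(NA_integer_, dim(roi))
  lv[roi] <- radrep:::bin_intensities(volume[roi], bins)
  dm <- dim(roi)
  seen <- array(FALSE, dm)
  offs <- radrep:::neighbor_offsets26()
  zones <- list()
  for (start in which(roi)) {
    if (seen[start]) next
    b <- lv[start]
    stack <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      ci <- arrayInd(cur, dm)
      for (r in seq_len(nrow(offs))) {
        p <- ci + offs[r, ]
        if (any(p < 1) || any(p > dm)) next
        lin <- p[1] + (p[2] - 1) * dm[1] + (p[3] - 1) * dm[1] * dm[2]
        if (seen[lin] || is.na(lv[lin]) || lv[lin] != b) next
        seen[lin] <- TRUE
        stack <- c(stack, lin)
      }
    }
    zones[[length(zones) + 1L]] <- c(bin = b, size = size)
  }
  do.call(rbind, zones)
}

# ICC(2,1) oracle through R's ANOVA machinery.
icc_anova_oracle <- function(x, y) {
  n <- length(x)
  df <- data.frame(v = c(x, y), subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  a <- stats::anova(stats::aov(v ~ subj + rater, data = df))
  msr <- a["subj", "Mean Sq"]
  msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse + 2 / n * (msc - mse))
}
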