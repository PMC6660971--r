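test_that("box-counting dimension recovers solid and planar limits", {
  cube <- array(TRUE, c(16, 16, 16))
  f <- fractal_features(cube, array(100, c(16, 16, 16)))
  bd <- unname(f$values["fractal.boxdim"])
  expect_gte(bd, 2.8)
  expect_lte(bd, 3.0 + 1e-9)
  plane <- array(FALSE, c(16, 16, 3)); plane[, , 2] <- TRUE
  fp <- fractal_features(plane, array(100, c(16, 16, 3)))
  bdp <- unname(fp$values["fractal.boxdim"])
  expect_gte(bdp, 1.8)
  expect_lte(bdp, 2.2)
})

test_that("flat intensity surfaces have blanket signature 2 and lacunarity 1", {
  cube <- array(TRUE, c(12, 12, 12))
  f <- fractal_features(cube, array(55, c(12, 12, 12)))
  fsd <- f$values[grep("fsd", names(f$values))]
  expect_equal(unname(fsd), rep(2, 7), tolerance = 1e-12)
  lac <- f$values[grep("lacunarity", names(f$values))]
  expect_equal(unname(lac), rep(1, 7))
})

test_that("tiny masks fail the fractal family with too_few_voxels", {
  m <- array(FALSE, c(6, 6, 6)); m[3:4, 3:4, 3:4] <- TRUE
  f <- fractal_features(m, array(rnorm(216), c(6, 6, 6)))
  expect_true(all(f$failure == "too_few_voxels"))
})

test_that("margin slope increases monotonically as the margin sharpens", {
  slopes <- vapply(c(2.5, 1.0, 0.2), function(mw) {
    cs <- make_sphere_case(12, c(1, 1, 1), margin_width = mw, seed = 5)
    b <- sigmoid_margin_features(cs$volume, cs$mask, cs$spacing)
    unname(b$values["sigmoid.l5.slope_mean"])
  }, numeric(1))
  expect_true(all(diff(slopes) > 0))
  expect_true(all(slopes > 0))               # intensity rises inward
})

test_that("edge-free volumes and single voxels fail the sigmoid family", {
  cs <- make_sphere_case(10, c(1, 1, 1))
  uniform <- array(50, dim(cs$volume))
  b <- sigmoid_margin_features(uniform, cs$mask, cs$spacing)
  expect_true(all(b$failure == "fit_nonconvergence"))
  m1 <- array(FALSE, c(9, 9, 9)); m1[5, 5, 5] <- TRUE
  b1 <- sigmoid_margin_features(array(rnorm(729), c(9, 9, 9)), m1, c(1, 1, 1))
  expect_true(all(b1$failure == "too_few_voxels"))
})

test_that("sigmoid fitting is deterministic", {
  cs <- make_sphere_case(10, c(1, 1, 1), margin_width = 1.2, noise_sd = 15,
                         texture_amplitude = 30, seed = 6)
  b1 <- sigmoid_margin_features(cs$volume, cs$mask, cs$spacing)
  b2 <- sigmoid_margin_features(cs$volume, cs$mask, cs$spacing)
  expect_identical(b1, b2)
})

test_that("LoG response of a constant volume is zero with unit uniformity", {
  b <- log_filter_features(array(7, c(12, 12, 12)), array(TRUE, c(12, 12, 12)))
  expect_equal(unname(b$values["log.s1.0.mean"]), 0, tolerance = 1e-6)
  expect_equal(unname(b$values["log.s1.0.sd"]), 0, tolerance = 1e-6)
  expect_equal(unname(b$values["log.s1.0.entropy"]), 0)
  expect_equal(unname(b$values["log.s1.0.uniformity"]), 1)
})

test_that("LoG response of a matched Gaussian blob peaks (in magnitude) at its centre", {
  n <- 25; sig <- 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  ctr <- (n + 1) / 2
  blob <- array(exp(-((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2) /
                      (2 * sig^2)), c(n, n, n))
  k <- radrep:::log_kernel3(sig)
  pad <- radrep:::pad_replicate3(blob, (dim(k)[1] - 1) %/% 2)
  conv <- radrep:::fftconv3(pad, k)
  w <- (dim(k)[1] - 1) %/% 2
  resp <- conv[w + seq_len(n), w + seq_len(n), w + seq_len(n)]
  expect_equal(which.min(resp), which.max(blob))  # strongest negative response
})

test_that("symmetric intensity samples give zero LoG skewness", {
  resp <- c(-4, -2, 0, 2, 4)
  s <- radrep:::log_response_stats(resp)
  expect_equal(unname(s["skewness"]), 0)
})
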