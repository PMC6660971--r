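test_that("GLCM matrix equals the brute-force co-occurrence oracle", {
  withr::with_seed(13, {
    for (rep in 1:3) {
      vol <- array(sample(0:300, 125, replace = TRUE), c(5, 5, 5))
      roi <- array(runif(125) > 0.2, c(5, 5, 5))
      if (sum(roi) < 2) next
      P <- glcm_matrix(vol, roi, 8)
      O <- glcm_bruteforce(vol, roi, 8)
      expect_lt(max(abs(P - O)), 1e-9)
    }
  })
})

test_that("degenerate GLCM inputs follow their exact limits", {
  # constant ROI: single nonzero entry
  P <- glcm_matrix(array(5, c(3, 3, 3)), array(TRUE, c(3, 3, 3)), 8)
  expect_equal(P[1, 1], 1)
  expect_equal(sum(P), 1)
  f <- glcm_features(P)
  expect_equal(unname(f[c("entropy", "contrast", "dissimilarity")]), c(0, 0, 0))
  expect_equal(unname(f[c("energy", "homogeneity")]), c(1, 1))
  # two voxels in different bins: symmetric 0.5/0.5
  vol <- array(c(0, 100), c(2, 1, 1))
  P2 <- glcm_matrix(vol, array(TRUE, c(2, 1, 1)), 2)
  expect_equal(P2[1, 2], 0.5)
  expect_equal(P2[2, 1], 0.5)
  # no in-ROI neighbour pair
  roi <- array(FALSE, c(5, 5, 5)); roi[1, 1, 1] <- TRUE; roi[5, 5, 5] <- TRUE
  expect_null(glcm_matrix(array(1:125, c(5, 5, 5)), roi, 4))
})

test_that("GLCM measures match hand computation on a 2x2 matrix", {
  P <- matrix(0.25, 2, 2)
  f <- glcm_features(P)
  expect_equal(unname(f["entropy"]), 2)
  expect_equal(unname(f["difference_entropy"]), 1)  # P_{x-y} = {0.5, 0.5}
  expect_equal(unname(f["energy"]), 0.25)
  expect_equal(unname(f["contrast"]), 0.5)
  expect_equal(unname(f["correlation"]), 0)
})

test_that("GLCM correlation stays within [-1, 1] on random matrices", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      M <- matrix(stats::rexp(16), 4, 4)
      M <- M + t(M)
      f <- glcm_features(M / sum(M))
      expect_gte(unname(f["correlation"]), -1 - 1e-12)
      expect_lte(unname(f["correlation"]), 1 + 1e-12)
    }
  })
})

test_that("whole-ROI GLCM features of a textured nodule equal the oracle", {
  cs <- make_sphere_case(6, c(1, 1, 1), texture_amplitude = 50,
                         noise_sd = 10, seed = 21)
  bb <- radrep:::mask_bbox(cs$mask)
  vol <- radrep:::crop_bbox(cs$volume, bb)
  roi <- radrep:::crop_bbox(cs$mask, bb)
  expect_lte(max(dim(roi)), 6)
  P <- glcm_matrix(vol, roi, 16)
  O <- glcm_bruteforce(vol, roi, 16)
  expect_lt(max(abs(P - O)), 1e-9)
  expect_lt(max(abs(glcm_features(P) - glcm_features(O))), 1e-9)
})

test_that("GLCM family delta vanishes on homogeneous nodules and fails small ones", {
  cs <- make_sphere_case(12, c(1, 1, 1), noise_sd = 0)
  p <- partition_roi(cs)
  blk <- glcm_family(p, cs$volume)
  delta <- blk$values[grep("glcm\\.delta", names(blk$values))]
  expect_equal(unname(delta), rep(0, 11))
  # 8-voxel nodule: sub-sampled family collapses
  m <- array(FALSE, c(6, 6, 6)); m[3:4, 3:4, 3:4] <- TRUE
  cs8 <- image_case("c8", array(rnorm(216), c(6, 6, 6)), m, c(1, 1, 1))
  p8 <- partition_roi(cs8)
  b8 <- glcm_family(p8, cs8$volume, subsample = TRUE)
  expect_true(all(b8$failure != "none"))
})

test_that("ISZM zones follow exact counting limits and the oracle", {
  # constant ROI: one zone covering n voxels
  b <- iszm_features(array(7, c(3, 3, 2)), array(TRUE, c(3, 3, 2)))
  expect_equal(unname(b$values), c(1 / 18, 18^2))
  # all-distinct values: every zone has size 1
  vd <- array(seq_len(27) * 50, c(3, 3, 3))
  bd <- iszm_features(vd, array(TRUE, c(3, 3, 3)),
                      binning_spec(iszm_bins = 32))
  expect_equal(unname(bd$values["iszm.large_zone_emphasis"]), 1)
  # zone sizes partition the ROI (pre-capping)
  withr::with_seed(31, {
    vol <- array(sample(1:5, 64, replace = TRUE) * 40, c(4, 4, 4))
    roi <- array(runif(64) > 0.25, c(4, 4, 4))
    zs <- iszm_bruteforce_sizes(vol, roi, 5)
    expect_equal(sum(zs[, "size"]), sum(roi))
    Z <- iszm_matrix(vol, roi, 5)
    expect_equal(sum(Z), nrow(zs))
    for (r in seq_len(nrow(zs)))
      expect_gte(Z[zs[r, "bin"], zs[r, "size"]], 1)
  })
})

test_that("NGTDM features agree with brute-force enumeration", {
  withr::with_seed(17, {
    vol <- array(sample(1:200, 27, replace = TRUE), c(3, 3, 3))
    roi <- array(TRUE, c(3, 3, 3))
    M <- ngtdm_matrix(vol, roi, 8)
    O <- ngtdm_bruteforce(vol, roi, 8)
    expect_equal(M$s_i, O$s_i, tolerance = 1e-12)
    expect_identical(M$n_i, O$n_i)
    expect_identical(M$n_valid, 1L)            # only the centre voxel
    # larger irregular ROI
    vol6 <- array(sample(1:500, 216, replace = TRUE), c(6, 6, 6))
    roi6 <- array(runif(216) > 0.15, c(6, 6, 6))
    M6 <- ngtdm_matrix(vol6, roi6, 8)
    O6 <- ngtdm_bruteforce(vol6, roi6, 8)
    if (!is.null(M6)) {
      expect_lt(max(abs(M6$s_i - O6$s_i)), 1e-9)
      expect_identical(M6$n_i, O6$n_i)
    }
  })
})

test_that("NGTDM has exact degenerate limits and failure contract", {
  b <- ngtdm_features(array(5, c(4, 4, 4)), array(TRUE, c(4, 4, 4)))
  expect_equal(unname(b$values["ngtdm.contrast"]), 0)
  expect_equal(unname(b$values["ngtdm.coarseness"]), 1e12)
  roi2 <- array(FALSE, c(3, 3, 3)); roi2[1:2] <- TRUE
  b2 <- ngtdm_features(array(rnorm(27), c(3, 3, 3)), roi2)
  expect_true(all(b2$failure == "too_few_voxels"))
})

test_that("families that succeed on a mask succeed on supersets (nested spheres)", {
  inner <- make_sphere_case(7, c(1, 1, 1), texture_amplitude = 30, seed = 8)
  # superset: same grid, larger radius around the same centre
  spec_big <- nodule_spec(10, texture_amplitude = 30)
  outer <- generate_case(spec_big, c(1, 1, 1),
                         grid_shape = dim(inner$volume), seed = 8)
  n_inner <- ngtdm_features(inner$volume, inner$mask)
  if (all(n_inner$failure == "none")) {
    n_outer <- ngtdm_features(inner$volume, outer$mask)
    expect_true(all(n_outer$failure == "none"))
  }
  p_in <- partition_roi(inner)
  g_in <- glcm_family(p_in, inner$volume, subsample = TRUE)
  if (all(g_in$failure[grep("whole", names(g_in$failure))] == "none")) {
    cs_out <- image_case("o", inner$volume, outer$mask, c(1, 1, 1))
    g_out <- glcm_family(partition_roi(cs_out), inner$volume, subsample = TRUE)
    expect_true(all(g_out$failure[grep("whole", names(g_out$failure))] == "none"))
  }
})
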