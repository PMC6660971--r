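test_that("the roster has exactly 252 unique names with the stated family counts", {
  r <- feature_roster()
  expect_length(r, 252)
  expect_equal(anyDuplicated(r), 0L)
  fam <- radrep:::feature_family_of(r)
  expect_equal(as.integer(table(fam)[c("histogram", "shape", "sigmoid", "fractal",
                                   "glcm", "glcmsub", "iszm", "ngtdm", "log")]),
               c(60L, 13L, 6L, 15L, 44L, 44L, 2L, 5L, 63L))
})

test_that("a large nodule yields a complete 252-feature vector", {
  fv <- fixture("large_fv", extract_all(large_nodule()))
  expect_length(fv$values, 252)
  expect_true(all(fv$failure == "none"))
  expect_equal(sum(grepl("^glcm\\.", names(fv$values))), 44)
  expect_equal(sum(grepl("^glcmsub\\.", names(fv$values))), 44)
})

test_that("a tiny nodule fails the neighbourhood families but keeps histogram/shape", {
  tiny <- resample_isotropic(make_sphere_case(4, c(0.7, 0.7, 1.5), seed = 3), 2)
  fv <- extract_all(tiny)
  expect_true(all(fv$failure[grep("^ngtdm\\.", names(fv$failure))] != "none"))
  expect_true(all(fv$failure[grep("^glcmsub\\.", names(fv$failure))] != "none"))
  expect_true(all(fv$failure[grep("^hist\\.whole\\.", names(fv$failure))] == "none"))
  expect_true(all(fv$failure[grep("^shape3d\\.", names(fv$failure))] == "none"))
})

test_that("extraction is deterministic", {
  cs <- make_sphere_case(9, c(1.2, 1.2, 2), noise_sd = 15,
                         texture_amplitude = 30, seed = 12)
  expect_identical(extract_all(cs), extract_all(cs))
})

test_that("features are invariant to translating the nodule in the grid", {
  # margin > 7 mm line half-length + shift keeps every sampling line in-grid
  cs <- make_sphere_case(9, c(1.5, 1.5, 1.5), noise_sd = 10,
                         texture_amplitude = 30, margin_width = 1, seed = 14,
                         grid_margin = 11)
  sh <- c(2L, -1L, 1L)
  cs2 <- image_case(cs$case_id,
                    radrep:::shift3(cs$volume, sh, -850),
                    radrep:::shift3(cs$mask, sh, FALSE),
                    cs$spacing)
  fv1 <- extract_all(cs)
  fv2 <- extract_all(cs2)
  ok <- fv1$failure == "none" & fv2$failure == "none"
  rel <- abs(fv1$values[ok] - fv2$values[ok]) /
    pmax(abs(fv1$values[ok]), 1)
  # LoG support can reach the (changed) grid border; everything else exact
  lg <- grepl("^log\\.", names(rel))
  expect_lt(max(rel[!lg]), 1e-8)
  expect_lt(max(rel[lg]), 0.05)
})

test_that("features are invariant to in-plane 90-degree rotation", {
  cs <- make_sphere_case(9, c(1.5, 1.5, 1.5), noise_sd = 10,
                         texture_amplitude = 30, margin_width = 1, seed = 15,
                         grid_margin = 9)
  rot90 <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  cs2 <- image_case(cs$case_id, rot90(cs$volume), rot90(cs$mask), cs$spacing)
  fv1 <- extract_all(cs)
  fv2 <- extract_all(cs2)
  ok <- fv1$failure == "none" & fv2$failure == "none"
  rel <- abs(fv1$values[ok] - fv2$values[ok]) / pmax(abs(fv1$values[ok]), 1)
  expect_lt(max(rel), 1e-6)
})

test_that("restricting families restricts the roster accordingly", {
  cs <- make_sphere_case(8, c(1.5, 1.5, 1.5), seed = 16)
  fv <- extract_all(cs, families = c("histogram", "shape"))
  expect_length(fv$values, 73)
  expect_true(all(grepl("^(hist|shape)", names(fv$values))))
})
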