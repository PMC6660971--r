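# Table-level fixtures: audit logic operates on feature tables, so the
# groups can be simulated directly without rendering image volumes.

audit_toy_table <- function(vol_error, vol_nonerror, ngtdm_failed_idx) {
  n <- length(vol_error) + length(vol_nonerror)
  tab <- data.frame(case_id = sprintf("c%03d", seq_len(n)),
                    setting_id = "orig",
                    shape3d.volume = c(vol_error, vol_nonerror),
                    hist.whole.mean = rnorm(n),
                    ngtdm.coarseness = rnorm(n))
  tab$ngtdm.coarseness[ngtdm_failed_idx] <- NA
  fail <- matrix("none", n, 3,
                 dimnames = list(tab$case_id,
                                 c("shape3d.volume", "hist.whole.mean",
                                   "ngtdm.coarseness")))
  fail[ngtdm_failed_idx, "ngtdm.coarseness"] <- "too_few_voxels"
  attr(tab, "failure") <- fail
  tab
}

test_that("error groups are exactly the cases with failed family features", {
  ch <- generate_cohort(cohort_config(n_cases = 16,
                                      small_nodule_fraction = 0.375,
                                      rng_seed = 33L))
  # at the isotropic 2 mm setting sub-5.5 mm nodules span too few voxels
  # for any complete 26-neighbourhood, so NGTDM must fail on all of them
  tab <- extract_table(ch, setting_id = "iso", resample_to = 2,
                       families = c("histogram", "shape", "ngtdm"))
  g <- split_error_groups(tab, "ngtdm")
  small_ids <- ch$truth$case_id[ch$truth$small_nodule]
  # every planted-small nodule must be in the error group
  expect_true(all(small_ids %in% g$error))
  # error-group nodules are systematically smaller
  expect_lt(max(ch$truth$equivalent_diameter[ch$truth$case_id %in% g$error]),
            min(ch$truth$equivalent_diameter[!ch$truth$case_id %in% g$error]) + 3)
})

test_that("single-group situations skip the comparison with a warning", {
  withr::with_seed(41, {
    tab_ok <- audit_toy_table(numeric(0), rnorm(8, 1000, 50), integer(0))
    expect_warning(out <- run_failure_audit(tab_ok, "ngtdm"), "one group")
    expect_null(out$comparisons)
    tab_bad <- audit_toy_table(rnorm(8, 400, 50), numeric(0), 1:8)
    expect_warning(out2 <- run_failure_audit(tab_bad, "ngtdm"), "one group")
    expect_null(out2$comparisons)
  })
})

test_that("Welch t and the non-error CI match closed-form hand computation", {
  xe <- c(1, 2, 3)            # error group
  xo <- c(1000, 1200, 1400)   # non-error group
  tab <- audit_toy_table(xe, xo, 1:3)
  g <- split_error_groups(tab, "ngtdm")
  cmp <- compare_groups(tab, g, features = "shape3d.volume")
  se <- sqrt(var(xe) / 3 + var(xo) / 3)
  t_hand <- (mean(xo) - mean(xe)) / se
  expect_equal(cmp$t_statistic, t_hand, tolerance = 1e-12)
  half <- qt(0.975, 2) * sd(xo) / sqrt(3)
  expect_equal(cmp$ci95_lo, 1200 - half, tolerance = 1e-12)
  expect_equal(cmp$ci95_hi, 1200 + half, tolerance = 1e-12)
  expect_equal(cmp$direction_tested, "nonerror_greater")
  df_welch <- se^4 / ((var(xe) / 3)^2 / 2 + (var(xo) / 3)^2 / 2)
  expect_equal(cmp$one_sided_p, pt(t_hand, df_welch, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("one-tailed tests have calibrated type-I error under the null", {
  p_reject <- withr::with_seed(42, {
    mean(vapply(1:1000, function(i) {
      xe <- rnorm(20, 500, 100)
      xo <- rnorm(25, 500, 100)
      tab <- audit_toy_table(xe, xo, seq_along(xe))
      g <- split_error_groups(tab, "ngtdm")
      cmp <- compare_groups(tab, g, features = "shape3d.volume",
                            direction = "nonerror_greater")
      cmp$one_sided_p < 0.05
    }, logical(1)))
  })
  expect_lt(abs(p_reject - 0.05), 0.02)
})

test_that("a planted 2.5x volume difference is detected with high power", {
  detected <- withr::with_seed(43, {
    vapply(1:60, function(i) {
      xe <- rnorm(50, 470, 150)
      xo <- rnorm(50, 1229, 300)
      tab <- audit_toy_table(xe, xo, 1:50)
      g <- split_error_groups(tab, "ngtdm")
      cmp <- compare_groups(tab, g, features = "shape3d.volume")
      cmp$one_sided_p < 0.05
    }, logical(1))
  })
  expect_gte(mean(detected), 0.95)
})

test_that("volume guidelines come from the non-error CI lower bound", {
  withr::with_seed(44, {
    xo <- rnorm(50, 1200, 150)
    tab <- audit_toy_table(rnorm(20, 400, 100), xo, 1:20)
    out <- run_failure_audit(tab, "ngtdm")
    gl <- out$guidelines[out$guidelines$feature == "shape3d.volume", ]
    half <- qt(0.975, 49) * sd(xo) / sqrt(50)
    expect_equal(gl$ci95_lo, mean(xo) - half, tolerance = 1e-10)
    expect_equal(gl$guideline, floor(gl$ci95_lo / 10) * 10)
    expect_gte(gl$ci95_lo, 1100)
    expect_lte(gl$ci95_lo, 1200)
  })
  # deterministic toy
  tab <- audit_toy_table(c(10, 20, 30), c(1000, 1200, 1400), 1:3)
  out <- run_failure_audit(tab, "ngtdm")
  gl <- out$guidelines[out$guidelines$feature == "shape3d.volume", ]
  expect_equal(gl$ci95_lo, 1200 - qt(0.975, 2) * 200 / sqrt(3),
               tolerance = 1e-10)
})

test_that("group assignment partitions the audited cases", {
  withr::with_seed(45, {
    tab <- audit_toy_table(rnorm(5, 400, 50), rnorm(7, 1200, 100), 1:5)
    g <- split_error_groups(tab, "ngtdm")
    expect_setequal(c(g$error, g$nonerror), tab$case_id)
    expect_length(intersect(g$error, g$nonerror), 0)
  })
})
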