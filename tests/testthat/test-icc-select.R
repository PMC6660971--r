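test_that("ICC matches the direct ANOVA mean-squares oracle", {
  x <- c(1, 2, 3, 4); y <- c(4, 3, 2, 1)
  expect_equal(icc(x, y), icc_anova_oracle(x, y), tolerance = 1e-12)
  withr::with_seed(21, {
    for (rep in 1:5) {
      a <- rnorm(15)
      b <- 0.8 * a + rnorm(15, 0, 0.5)
      expect_equal(icc(a, b), icc_anova_oracle(a, b), tolerance = 1e-10)
    }
  })
})

test_that("ICC has its exact agreement limits", {
  expect_equal(icc(1:10, 1:10), 1)
  expect_equal(icc(rep(5, 6), rep(5, 6)), 1)   # zero variance: defined as 1
  expect_true(is.na(icc(c(1, 2), c(1, 2))))    # fewer than 3 pairs
  x <- rnorm(30)
  expect_lt(icc(x, x + 10 * sd(x)), 0.5)       # absolute agreement penalizes offset
})

test_that("ICC is symmetric and invariant to a shared positive affine map", {
  withr::with_seed(3, {
    x <- rnorm(25); y <- x + rnorm(25, 0, 0.3)
    expect_equal(icc(x, y), icc(y, x), tolerance = 1e-12)
    expect_equal(icc(3 * x + 7, 3 * y + 7), icc(x, y), tolerance = 1e-10)
  })
})

test_that("ICC drops incomplete pairs before computing", {
  x <- c(1, 2, 3, 4, NA)
  y <- c(1.1, 2.2, 2.9, 4.1, 7)
  expect_equal(icc(x, y), icc(x[1:4], y[1:4]))
})

test_that("screening a table against itself passes all non-constant features", {
  tab <- data.frame(case_id = sprintf("c%d", 1:8), setting_id = "a",
                    f1 = rnorm(8), f2 = rnorm(8))
  s <- icc_screen(tab, transform(tab, setting_id = "b"))
  expect_setequal(s$pass, c("f1", "f2"))
  expect_equal(unname(s$icc), c(1, 1))
  s2 <- icc_screen(tab, transform(tab, setting_id = "b"), threshold = 1.01)
  expect_length(s2$pass, 0)
})

test_that("an independent-noise feature fails the 0.7 screen with high probability", {
  fails <- withr::with_seed(77, {
    vapply(1:200, function(i) {
      x <- rnorm(180); y <- rnorm(180)
      v <- icc(x, y)
      !is.na(v) && v < 0.7
    }, logical(1))
  })
  expect_gte(mean(fails), 0.99)
})

test_that("LASSO recovers a single separating feature among noise", {
  withr::with_seed(101, {
    n <- 200
    X <- matrix(rnorm(n * 21), n, 21)
    y <- ifelse(X[, 1] + rnorm(n, 0, 0.5) > 0, "malignant", "benign")
    tab <- cbind(data.frame(case_id = sprintf("c%d", 1:n), setting_id = "s"),
                 as.data.frame(X))
    colnames(tab)[-(1:2)] <- paste0("f", 1:21)
    sel <- lasso_select(tab, y, seed = 5)
    expect_true("f1" %in% sel)
  })
})

test_that("permuted labels mostly yield near-empty LASSO selections", {
  sizes <- withr::with_seed(55, {
    n <- 120
    X <- matrix(rnorm(n * 15), n, 15)
    y <- rep(c("benign", "malignant"), each = n / 2)
    vapply(1:10, function(i) {
      yp <- sample(y)
      tab <- cbind(data.frame(case_id = sprintf("c%d", 1:n), setting_id = "s"),
                   as.data.frame(X))
      colnames(tab)[-(1:2)] <- paste0("f", 1:15)
      suppressWarnings(length(lasso_select(tab, yp, seed = i)))
    }, numeric(1))
  })
  expect_gte(mean(sizes <= 2), 0.6)
  expect_lt(stats::median(sizes), 2)
})

test_that("duplicated informative columns keep at least one representative", {
  withr::with_seed(9, {
    n <- 150
    x <- rnorm(n)
    y <- ifelse(x + rnorm(n, 0, 0.4) > 0, "malignant", "benign")
    tab <- data.frame(case_id = sprintf("c%d", 1:n), setting_id = "s",
                      a = x, b = x, n1 = rnorm(n))
    sel <- lasso_select(tab, y, seed = 2)
    expect_true(any(c("a", "b") %in% sel))
  })
})

test_that("signature intersection is an ordered set intersection", {
  r <- feature_roster()
  sel <- list(s1 = r[c(5, 1, 9)], s2 = r[c(9, 5, 20)])
  expect_identical(intersect_signatures(sel), r[c(5, 9)])
  expect_identical(intersect_signatures(list(r[1:3], r[1:3])), r[1:3])
  expect_warning(out <- intersect_signatures(list(r[1:2], r[5:6])), "empty")
  expect_length(out, 0)
})

test_that("screen-then-select nesting holds on a synthetic table", {
  withr::with_seed(31, {
    n <- 80
    base <- matrix(rnorm(n * 6), n, 6)
    y <- ifelse(base[, 1] - base[, 2] + rnorm(n, 0, 0.7) > 0,
                "malignant", "benign")
    mk <- function(noise) {
      tab <- cbind(data.frame(case_id = sprintf("c%d", 1:n), setting_id = "x"),
                   as.data.frame(base + matrix(rnorm(n * 6, 0, noise), n, 6)))
      colnames(tab)[-(1:2)] <- paste0("f", 1:6)
      tab
    }
    ta <- mk(0.05); tb <- mk(0.05)
    screen <- icc_screen(ta, tb)
    sa <- suppressWarnings(lasso_select(ta, y, screen$pass, seed = 1))
    sb <- suppressWarnings(lasso_select(tb, y, screen$pass, seed = 1))
    sig <- if (length(sa) && length(sb))
      suppressWarnings(intersect_signatures(list(sa, sb))) else character()
    expect_true(all(sa %in% screen$pass))
    expect_true(all(sb %in% screen$pass))
    expect_true(all(sig %in% sa) && all(sig %in% sb))
  })
})
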