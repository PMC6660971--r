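toy_table <- function(X, prefix = "f") {
  tab <- cbind(data.frame(case_id = sprintf("c%d", seq_len(nrow(X))),
                          setting_id = "s"), as.data.frame(X))
  colnames(tab)[-(1:2)] <- paste0(prefix, seq_len(ncol(X)))
  tab
}

test_that("metrics on a hand-built separable score set are exact", {
  m <- classification_metrics(c(0.9, 0.8, 0.4, 0.1),
                              c("malignant", "malignant", "benign", "benign"))
  expect_equal(m$auc, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  # metrics recompute exactly from the stored confusion matrix
  cm <- m$confusion
  expect_equal(m$sensitivity, cm["malignant", "malignant"] /
                 sum(cm["malignant", ]))
  expect_equal(m$specificity, cm["benign", "benign"] / sum(cm["benign", ]))
  expect_equal(m$accuracy, sum(diag(cm)) / sum(cm))
})

test_that("trapezoidal AUC matches pROC and the ROC-point geometry", {
  withr::with_seed(8, {
    s <- runif(60)
    l <- ifelse(runif(60) < 0.4, "malignant", "benign")
    a1 <- auc_trapezoid(s, l)
    a2 <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(l, s, levels = c("benign", "malignant"),
                          direction = "<"))))
    expect_equal(a1, a2, tolerance = 1e-12)
    m <- classification_metrics(s, l)
    rp <- m$roc_points
    trap <- sum(diff(rp[, "fpr"]) *
                  (head(rp[, "tpr"], -1) + tail(rp[, "tpr"], -1)) / 2)
    expect_equal(m$auc, trap, tolerance = 1e-12)
  })
})

test_that("AUC is invariant to strictly monotone transforms of the scores", {
  withr::with_seed(9, {
    s <- runif(50)
    l <- ifelse(runif(50) < 0.5, "malignant", "benign")
    expect_equal(auc_trapezoid(s, l), auc_trapezoid(qlogis(s), l))
    expect_equal(auc_trapezoid(s, l), auc_trapezoid(s^3, l))
  })
})

test_that("label-independent scores give null AUC on average", {
  aucs <- withr::with_seed(10, {
    vapply(1:200, function(i) {
      auc_trapezoid(runif(80), rep(c("benign", "malignant"), 40))
    }, numeric(1))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("random-forest training and evaluation are seed-deterministic", {
  withr::with_seed(11, {
    X <- matrix(rnorm(200 * 3), 200, 3)
    y <- ifelse(X[, 1] > 0, "malignant", "benign")
    tab <- toy_table(X)
  })
  m1 <- train_rf(tab, y, c("f1", "f2", "f3"), seed = 3)
  m2 <- train_rf(tab, y, c("f1", "f2", "f3"), seed = 3)
  e1 <- evaluate_classifier(m1, tab, y)
  e2 <- evaluate_classifier(m2, tab, y)
  expect_identical(e1$auc, e2$auc)
  expect_identical(oob_importance(m1), oob_importance(m2))
  expect_equal(m1$ntree, 200)
})

test_that("well-separated planted classes reach high OOB AUC; identical features do not", {
  withr::with_seed(12, {
    n <- 200
    X <- matrix(rnorm(n * 2), n, 2)
    y <- ifelse(X[, 1] * 2 + rnorm(n, 0, 0.4) > 0, "malignant", "benign")
    tab <- toy_table(X)
    model <- train_rf(tab, y, c("f1", "f2"), seed = 4)
    oob <- predict(model, type = "prob")[, "malignant"]
    expect_gte(auc_trapezoid(oob, y), 0.9)
    # class-independent features
    y0 <- rep(c("benign", "malignant"), n / 2)
    m0 <- train_rf(tab, y0, c("f1", "f2"), seed = 4)
    oob0 <- predict(m0, type = "prob")[, "malignant"]
    expect_lt(abs(auc_trapezoid(oob0, y0) - 0.5), 0.15)
  })
})

test_that("single-class training data is a training error", {
  tab <- toy_table(matrix(rnorm(20), 10, 2))
  expect_error(train_rf(tab, rep("benign", 10), c("f1", "f2")),
               "training error")
})

test_that("a test set missing one class cannot be evaluated", {
  withr::with_seed(13, {
    X <- matrix(rnorm(40 * 2), 40, 2)
    y <- rep(c("benign", "malignant"), 20)
    tab <- toy_table(X)
    model <- train_rf(tab, y, c("f1", "f2"), seed = 1)
    expect_error(evaluate_classifier(model, tab[1:5, ], rep("benign", 5)),
                 "AUC undefined")
  })
})

test_that("OOB permutation importance ranks informative above noise features", {
  hits <- withr::with_seed(14, {
    vapply(1:10, function(i) {
      n <- 150
      X <- cbind(rnorm(n), rnorm(n))
      y <- ifelse(X[, 1] + rnorm(n, 0, 0.5) > 0, "malignant", "benign")
      model <- train_rf(toy_table(X), y, c("f1", "f2"), seed = i)
      imp <- oob_importance(model)
      imp["f1"] >= imp["f2"]
    }, logical(1))
  })
  expect_gte(mean(hits), 0.9)
})

test_that("a single-feature model concentrates all importance on it", {
  withr::with_seed(15, {
    X <- matrix(rnorm(100), 100, 1)
    y <- ifelse(X[, 1] > 0, "malignant", "benign")
    model <- train_rf(toy_table(X), y, "f1", seed = 1)
    imp <- oob_importance(model)
    expect_length(imp, 1)
    expect_gt(imp[["f1"]], 0)
  })
})
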