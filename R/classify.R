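# Signature validation with a 200-tree random forest and threshold-free
# ROC metrics. Malignant is the positive class throughout.

#' Train a random forest on signature features
#'
#' 200 trees, floor(sqrt(p)) candidate predictors per split, seeded for
#' exact reproducibility; supports out-of-bag permutation importance.
#' Cases with failed signature values are dropped (complete-case).
#'
#' @param table feature table (typically z-scored).
#' @param status status labels aligned with the table.
#' @param features signature feature names.
#' @param n_trees number of trees (default 200).
#' @param seed RNG seed for the forest.
#' @return fitted `randomForest` model with the feature list attached.
#' @export
train_rf <- function(table, status, features, n_trees = 200, seed = 1L) {
  X <- as.data.frame(table[features])
  ok <- complete.cases(X)
  y <- factor(status[ok], levels = c("benign", "malignant"))
  if (length(unique(y)) < 2L)
    stop("training error: single-class training data", call. = FALSE)
  model <- withr::with_seed(seed,
    randomForest::randomForest(X[ok, , drop = FALSE], y, ntree = n_trees,
                               importance = TRUE))
  attr(model, "features") <- features
  model
}

#' Trapezoidal AUC of scores against binary labels
#'
#' Rank-based (Mann-Whitney) area with ties averaged; equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores predicted probabilities (or any monotone score).
#' @param labels factor/character with `"malignant"` positive.
#' @return AUC in \[0, 1\].
#' @export
auc_trapezoid <- function(scores, labels) {
  pos <- labels == "malignant"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: need both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(scores, labels) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- labels == "malignant"
  t(vapply(ths, function(th) {
    pred <- scores >= th
    c(fpr = sum(pred & !pos) / sum(!pos), tpr = sum(pred & pos) / sum(pos))
  }, numeric(2)))
}

#' Evaluate a trained classifier on a test table
#'
#' @param model a [train_rf()] model.
#' @param table test feature table (cases disjoint from training).
#' @param status test status labels.
#' @param threshold probability threshold for the confusion-matrix metrics.
#' @return object of class `classification_metrics` with `auc`, `accuracy`,
#'   `sensitivity`, `specificity`, the ROC points, the confusion matrix and
#'   the threshold used.
#' @export
evaluate_classifier <- function(model, table, status, threshold = 0.5) {
  features <- attr(model, "features")
  X <- as.data.frame(table[features])
  ok <- complete.cases(X)
  y <- factor(status[ok], levels = c("benign", "malignant"))
  if (length(unique(y)) < 2L)
    stop("AUC undefined: test set missing a class", call. = FALSE)
  prob <- predict(model, X[ok, , drop = FALSE], type = "prob")[, "malignant"]
  classification_metrics(prob, y, threshold = threshold,
                         n_dropped = sum(!ok))
}

#' Compute ROC metrics from scores and labels
#'
#' @param scores predicted malignancy probabilities.
#' @param labels status labels.
#' @param threshold operating point for accuracy/sensitivity/specificity.
#' @param n_dropped bookkeeping: cases dropped for failed values.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5,
                                   n_dropped = 0L) {
  labels <- factor(labels, levels = c("benign", "malignant"))
  pred <- scores >= threshold
  pos <- labels == "malignant"
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  structure(list(
    auc = auc_trapezoid(scores, labels),
    accuracy = (tp + tn) / length(labels),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    confusion = matrix(c(tn, fp, fn, tp), 2, 2,
                       dimnames = list(truth = c("benign", "malignant"),
                                       pred = c("benign", "malignant"))),
    roc_points = roc_points(scores, labels),
    threshold_used = threshold,
    scores = scores, labels = labels,
    n_dropped = n_dropped),
    class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("<classification_metrics> AUC %.4f  acc %.4f  sens %.4f  spec %.4f (threshold %.2f)\n",
              x$auc, x$accuracy, x$sensitivity, x$specificity,
              x$threshold_used))
  invisible(x)
}

#' Out-of-bag permutation importance of a trained forest
#'
#' Mean decrease in OOB accuracy under per-feature permutation, averaged
#' over trees (unscaled); deterministic under the training seed.
#'
#' @param model a [train_rf()] model.
#' @return named numeric vector of importance scores.
#' @export
oob_importance <- function(model) {
  imp <- randomForest::importance(model, type = 1, scale = FALSE)
  setNames(imp[, 1], rownames(imp))
}
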