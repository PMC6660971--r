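# Reproducibility screening. The ICC form is the two-way random-effects,
# absolute-agreement, single-measurement coefficient (the two extraction
# settings act as the "raters", and absolute agreement is what
# reproducibility demands).

#' Intraclass correlation (two-way random, absolute agreement, single)
#'
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE)) with k = 2
#' columns, from the standard two-way ANOVA mean squares. Incomplete pairs
#' are dropped; zero total variance (identical constant measurements)
#' gives ICC = 1 by definition.
#'
#' @param x,y paired measurements of the same cases under two settings.
#' @return ICC in (-Inf, 1], or NA when fewer than 3 complete pairs exist.
#' @export
icc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  M <- cbind(x, y)
  k <- 2L
  gm <- mean(M)
  if (all(M == M[1])) return(1)
  rm_ <- rowMeans(M)
  cm <- colMeans(M)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sse <- sum((M - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + gm)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom == 0) return(1)
  (msr - mse) / denom
}

#' Screen features by ICC across two settings
#'
#' @param table_a,table_b feature tables of the same cases under two
#'   settings (matched by `case_id`).
#' @param threshold retain features with ICC >= threshold (default 0.7).
#' @param features candidate feature names (default: all shared columns).
#' @return list of class `icc_screen` with `icc` (named vector),
#'   `pass` (feature names), `threshold` and `n_pairs` per feature.
#' @export
icc_screen <- function(table_a, table_b, threshold = 0.7, features = NULL) {
  if (is.null(features))
    features <- intersect(feature_cols(table_a), feature_cols(table_b))
  common <- intersect(table_a$case_id, table_b$case_id)
  if (length(common) < 3L)
    stop("need at least 3 shared cases for ICC screening", call. = FALSE)
  ia <- match(common, table_a$case_id)
  ib <- match(common, table_b$case_id)
  vals <- vapply(features, function(f) {
    xa <- table_a[[f]][ia]; xb <- table_b[[f]][ib]
    c(icc(xa, xb), sum(is.finite(xa) & is.finite(xb)))
  }, numeric(2))
  iccs <- setNames(vals[1, ], features)
  structure(list(icc = iccs,
                 pass = features[!is.na(iccs) & iccs >= threshold],
                 threshold = threshold,
                 n_pairs = setNames(vals[2, ], features)),
            class = "icc_screen")
}

#' @export
print.icc_screen <- function(x, ...) {
  cat(sprintf("<icc_screen> %d/%d features pass at ICC >= %.2f\n",
              length(x$pass), length(x$icc), x$threshold))
  invisible(x)
}

#' LASSO feature selection for nodule status
#'
#' L1-penalized logistic regression with the penalty chosen by 10-fold
#' stratified cross-validation at minimum mean deviance (fixed fold seed);
#' selected features are those with nonzero coefficients. Cases with any
#' failed candidate value are dropped (complete-case).
#'
#' @param table z-scored feature table.
#' @param status factor/character of case status aligned with the table.
#' @param features candidate features (e.g. an ICC pass set).
#' @param seed fold-assignment seed.
#' @param nfolds folds of the cross-validation.
#' @return character vector of selected features (possibly empty, with a
#'   warning when no penalty yields a nonzero model).
#' @export
lasso_select <- function(table, status, features = feature_cols(table),
                         seed = 1L, nfolds = 10L) {
  X <- as.matrix(table[features])
  ok <- complete.cases(X)
  X <- X[ok, , drop = FALSE]
  y <- factor(status[ok], levels = c("benign", "malignant"))
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stop("need at least 2 cases per class for LASSO selection", call. = FALSE)
  if (length(features) == 1L) X <- cbind(X, 0)  # glmnet needs >= 2 columns
  foldid <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
    }
  })
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                          foldid = foldid, standardize = FALSE)
  beta <- coef(cv, s = "lambda.min")[-1, 1]
  sel <- features[which(beta[seq_along(features)] != 0)]
  if (!length(sel))
    warning("LASSO selected no features at the CV-chosen penalty")
  sel
}

#' Intersect per-setting signature selections
#'
#' @param selections named list of feature-name vectors (one per setting).
#' @return intersection in roster order; empty with a warning when the
#'   selections share no feature.
#' @export
intersect_signatures <- function(selections) {
  stopifnot(length(selections) >= 2L)
  sig <- Reduce(intersect, selections)
  roster <- feature_roster()
  sig <- roster[roster %in% sig]
  if (!length(sig))
    warning("empty signature: selections share no feature")
  sig
}
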