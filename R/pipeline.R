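# End-to-end orchestration. The voxel-geometry experiment compares the
# native anisotropic setting against isotropic 2 mm resampling; the
# binning experiment fixes the isotropic setting and sweeps the GLCM gray
# levels {32, 64, 128} against the default 256, holding histogram (4096)
# and ISZM (32) binning at their defaults. Training and test cohorts are
# independent (external-validation design), and all stages are seeded.

#' Configure a pipeline run
#'
#' @param train,test cohort sources: a [cohort_config()] (synthetic) or a
#'   directory written by [write_cohort()].
#' @param iso_spacing isotropic resampling target in mm.
#' @param bins default [binning_spec()].
#' @param glcm_sweep GLCM gray-level sweep compared against the default.
#' @param icc_threshold ICC screening threshold.
#' @param max_failure_rate features whose failure fraction exceeds this in
#'   a training table are excluded before screening (the high-error-rate
#'   exclusion that leaves only reliably computable features in play).
#' @param lasso_seed,lasso_folds LASSO cross-validation fold seed / count.
#' @param rf_trees,rf_seed random-forest size and seed.
#' @param out_dir optional directory for persisted artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(train = cohort_config(rng_seed = 101L),
                       test = cohort_config(n_cases = 40, rng_seed = 202L),
                       iso_spacing = 2.0,
                       bins = binning_spec(),
                       glcm_sweep = c(32L, 64L, 128L),
                       icc_threshold = 0.7,
                       max_failure_rate = 0.2,
                       lasso_seed = 11L, lasso_folds = 10L,
                       rf_trees = 200L, rf_seed = 7L,
                       out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

load_cohort <- function(dir) {
  truth <- read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE)
  cases <- lapply(seq_len(nrow(truth)), function(i) {
    id <- truth$case_id[i]
    ip <- Sys.glob(file.path(dir, paste0(id, "_img.*")))[1]
    mp <- Sys.glob(file.path(dir, paste0(id, "_msk.*")))[1]
    load_case(ip, mp, status = truth$status[i], case_id = id)
  })
  structure(list(cases = cases, truth = truth, config = NULL),
            class = "radrep_cohort")
}

prepare_cohorts <- function(config) {
  get_one <- function(src) {
    if (inherits(src, "cohort_config")) generate_cohort(src)
    else if (is.character(src)) load_cohort(src)
    else stop("cohort source must be a cohort_config or a directory",
              call. = FALSE)
  }
  list(train = get_one(config$train), test = get_one(config$test))
}

persist_dir <- function(config, sub) {
  if (is.null(config$out_dir)) return(NULL)
  d <- file.path(config$out_dir, sub)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

persist_report <- function(report, dir) {
  if (is.null(dir)) return(invisible(NULL))
  icc_df <- data.frame(feature = names(report$icc$icc),
                       icc = unname(report$icc$icc))
  write.csv(icc_df, file.path(dir, "icc.csv"), row.names = FALSE)
  for (s in names(report$lasso_selected))
    writeLines(report$lasso_selected[[s]],
               file.path(dir, paste0("selected_", s, ".txt")))
  writeLines(report$signature, file.path(dir, "signature.txt"))
  for (s in names(report$metrics)) {
    m <- report$metrics[[s]]
    jsonlite::write_json(
      list(auc = m$auc, accuracy = m$accuracy,
           sensitivity = m$sensitivity, specificity = m$specificity),
      file.path(dir, paste0("metrics_", s, ".json")), auto_unbox = TRUE)
    write.csv(as.data.frame(m$roc_points),
              file.path(dir, paste0("roc_", s, ".csv")), row.names = FALSE)
  }
  invisible(NULL)
}

# Features computable reliably enough to analyze: failure fraction at or
# below the threshold in every supplied training table.
analyzable_features <- function(tabs, max_failure_rate) {
  fc <- Reduce(intersect, lapply(tabs, feature_cols))
  keep <- vapply(fc, function(f) {
    all(vapply(tabs, function(tb) mean(is.na(tb[[f]])), numeric(1)) <=
          max_failure_rate)
  }, logical(1))
  fc[keep]
}

new_signature_report <- function(icc, lasso_selected, signature, metrics,
                                 provenance) {
  structure(list(icc = icc, lasso_selected = lasso_selected,
                 signature = signature, metrics = metrics,
                 provenance = provenance),
            class = "signature_report")
}

#' @export
print.signature_report <- function(x, ...) {
  cat(sprintf("<signature_report> %s\n", x$provenance$experiment))
  cat(sprintf("  ICC pass: %d/%d at >= %.2f\n", length(x$icc$pass),
              length(x$icc$icc), x$icc$threshold))
  for (s in names(x$lasso_selected))
    cat(sprintf("  LASSO [%s]: %d features\n", s,
                length(x$lasso_selected[[s]])))
  cat(sprintf("  signature (%d): %s\n", length(x$signature),
              paste(x$signature, collapse = ", ")))
  for (s in names(x$metrics))
    cat(sprintf("  metrics [%s]: AUC %.4f acc %.4f sens %.4f spec %.4f\n", s,
                x$metrics[[s]]$auc, x$metrics[[s]]$accuracy,
                x$metrics[[s]]$sensitivity, x$metrics[[s]]$specificity))
  invisible(x)
}

select_and_validate <- function(config, screen, train_tabs, test_tabs,
                                train_status, test_status, experiment) {
  lasso_selected <- list()
  metrics <- list()
  for (s in names(train_tabs)) {
    norm <- zscore_normalize(train_tabs[[s]], test_tabs[[s]])
    cand <- intersect(screen$pass, feature_cols(norm$train))
    sel <- if (length(cand) >= 1L)
      tryCatch(lasso_select(norm$train, train_status, cand,
                            seed = config$lasso_seed,
                            nfolds = config$lasso_folds),
               error = function(e) { warning(conditionMessage(e)); character() })
    else character()
    lasso_selected[[s]] <- sel
  }
  signature <- if (all(lengths(lasso_selected) > 0))
    intersect_signatures(lasso_selected) else {
      warning("empty signature: a setting selected no features")
      character()
    }
  if (length(signature)) {
    for (s in names(train_tabs)) {
      norm <- zscore_normalize(train_tabs[[s]], test_tabs[[s]])
      sig_s <- intersect(signature, feature_cols(norm$train))
      model <- train_rf(norm$train, train_status, sig_s,
                        n_trees = config$rf_trees, seed = config$rf_seed)
      metrics[[s]] <- evaluate_classifier(model, norm$apply, test_status)
    }
  }
  new_signature_report(screen, lasso_selected, signature, metrics,
                       provenance = list(experiment = experiment,
                                         icc_threshold = config$icc_threshold,
                                         lasso_seed = config$lasso_seed,
                                         rf_seed = config$rf_seed))
}

#' Experiment 1: native vs. isotropic voxel geometry
#'
#' Extracts the full panel under the native and isotropic settings on the
#' training cohort, screens by ICC across the two settings, selects
#' per-setting LASSO signatures, intersects them, and validates each
#' setting's classifier on the independent test cohort.
#'
#' @param config a [run_config()].
#' @param cohorts optional precomputed [prepare_cohorts()] output.
#' @return a `signature_report` (metrics per voxel setting).
#' @export
run_experiment1 <- function(config = run_config(), cohorts = NULL) {
  if (is.null(cohorts)) cohorts <- prepare_cohorts(config)
  bins <- config$bins
  tr <- cohorts$train; te <- cohorts$test
  train_tabs <- list(
    orig = extract_table(tr, bins, "orig"),
    iso = extract_table(tr, bins, "iso", resample_to = config$iso_spacing))
  test_tabs <- list(
    orig = extract_table(te, bins, "orig"),
    iso = extract_table(te, bins, "iso", resample_to = config$iso_spacing))
  analyzable <- analyzable_features(train_tabs, config$max_failure_rate)
  screen <- icc_screen(train_tabs$orig, train_tabs$iso,
                       threshold = config$icc_threshold,
                       features = analyzable)
  report <- select_and_validate(config, screen, train_tabs, test_tabs,
                                tr$truth$status, te$truth$status,
                                "experiment1_voxel_geometry")
  persist_report(report, persist_dir(config, "exp1"))
  report
}

# Recompute only the GLCM families at sweep gray levels, splicing them
# into the default-bin table (all other families are bin-invariant here
# because histogram and ISZM stay at their default bins).
sweep_glcm_table <- function(default_tab, cases, sweep_bins, base_bins,
                             setting_id, resample_to) {
  b <- binning_spec(histogram_bins = base_bins$histogram_bins,
                    glcm_bins = sweep_bins, iszm_bins = base_bins$iszm_bins,
                    histogram_range = base_bins$histogram_range)
  gl <- extract_table(cases, b, setting_id, resample_to = resample_to,
                      families = c("glcm", "glcmsub"))
  out <- default_tab
  out$setting_id <- setting_id
  gcols <- feature_cols(gl)
  stopifnot(identical(gl$case_id, out$case_id))
  out[gcols] <- gl[gcols]
  fail <- attr(default_tab, "failure")
  fail[, gcols] <- attr(gl, "failure")[, gcols]
  attr(out, "failure") <- fail
  out
}

#' Experiment 2: GLCM gray-level sweeps at fixed voxel geometry
#'
#' At the isotropic setting, GLCM gray levels are swept over
#' `config$glcm_sweep` and each sweep is compared with the default
#' (256 levels) by ICC over the binning-dependent families (histogram,
#' GLCM, sub-sampled GLCM, ISZM; histogram and ISZM stay at their default
#' bins). Per-sweep LASSO selections are intersected into the signature
#' and validated per sweep.
#'
#' @inheritParams run_experiment1
#' @return a `signature_report` (metrics per sweep setting).
#' @export
run_experiment2 <- function(config = run_config(), cohorts = NULL) {
  if (is.null(cohorts)) cohorts <- prepare_cohorts(config)
  bins <- config$bins
  iso <- config$iso_spacing
  tr <- cohorts$train; te <- cohorts$test
  def_train <- extract_table(tr, bins, "glcm256", resample_to = iso)
  def_test <- extract_table(te, bins, "glcm256", resample_to = iso)
  analyzable <- analyzable_features(list(def_train), config$max_failure_rate)
  candidates <- grep("^(hist|glcm|glcmsub|iszm)\\.", analyzable, value = TRUE)
  train_tabs <- list(); test_tabs <- list(); screens <- list()
  for (b in config$glcm_sweep) {
    sid <- paste0("glcm", b)
    train_tabs[[sid]] <- sweep_glcm_table(def_train, tr, b, bins, sid, iso)
    test_tabs[[sid]] <- sweep_glcm_table(def_test, te, b, bins, sid, iso)
    screens[[sid]] <- icc_screen(def_train, train_tabs[[sid]],
                                 threshold = config$icc_threshold,
                                 features = candidates)
  }
  # merged screen: per sweep its own pass set feeds that sweep's LASSO
  lasso_selected <- list(); metrics <- list()
  for (sid in names(train_tabs)) {
    norm <- zscore_normalize(train_tabs[[sid]], test_tabs[[sid]])
    cand <- intersect(screens[[sid]]$pass, feature_cols(norm$train))
    sel <- if (length(cand) >= 1L)
      tryCatch(lasso_select(norm$train, tr$truth$status, cand,
                            seed = config$lasso_seed,
                            nfolds = config$lasso_folds),
               error = function(e) { warning(conditionMessage(e)); character() })
    else character()
    lasso_selected[[sid]] <- sel
  }
  signature <- if (all(lengths(lasso_selected) > 0))
    intersect_signatures(lasso_selected) else {
      warning("empty signature: a sweep selected no features")
      character()
    }
  if (length(signature)) {
    for (sid in names(train_tabs)) {
      norm <- zscore_normalize(train_tabs[[sid]], test_tabs[[sid]])
      sig_s <- intersect(signature, feature_cols(norm$train))
      model <- train_rf(norm$train, tr$truth$status, sig_s,
                        n_trees = config$rf_trees, seed = config$rf_seed)
      metrics[[sid]] <- evaluate_classifier(model, norm$apply, te$truth$status)
    }
  }
  icc_all <- do.call(c, lapply(names(screens), function(sid)
    setNames(screens[[sid]]$icc, paste(sid, names(screens[[sid]]$icc), sep = ":"))))
  screen_summary <- structure(
    list(icc = icc_all,
         pass = unique(unlist(lapply(screens, `[[`, "pass"))),
         threshold = config$icc_threshold,
         per_sweep = screens),
    class = "icc_screen")
  report <- new_signature_report(screen_summary, lasso_selected, signature,
                                 metrics,
                                 provenance = list(experiment = "experiment2_binning",
                                                   glcm_sweep = config$glcm_sweep,
                                                   icc_threshold = config$icc_threshold,
                                                   lasso_seed = config$lasso_seed,
                                                   rf_seed = config$rf_seed))
  persist_report(report, persist_dir(config, "exp2"))
  report
}

#' Run the full pipeline: both experiments plus the failure audit
#'
#' @param config a [run_config()].
#' @return list with `exp1`, `exp2`, `audit` (NGTDM and sub-sampled GLCM
#'   audits of the pooled default-setting tables) and a `manifest` of
#'   artifacts (written when `out_dir` is set).
#' @export
run_all <- function(config = run_config()) {
  cohorts <- prepare_cohorts(config)
  exp1 <- run_experiment1(config, cohorts)
  exp2 <- run_experiment2(config, cohorts)
  # audit on the native-setting training table (all families attempted)
  audit_tab <- extract_table(cohorts$train, config$bins, "orig")
  audits <- list(
    ngtdm = tryCatch(run_failure_audit(audit_tab, "ngtdm"),
                     warning = function(w) NULL, error = function(e) NULL),
    subsampled_glcm = tryCatch(run_failure_audit(audit_tab, "subsampled_glcm"),
                               warning = function(w) NULL,
                               error = function(e) NULL))
  manifest <- NULL
  if (!is.null(config$out_dir)) {
    ad <- persist_dir(config, "audit")
    for (fam in names(audits)) {
      if (is.null(audits[[fam]]) || is.null(audits[[fam]]$comparisons)) next
      write.csv(audits[[fam]]$comparisons,
                file.path(ad, paste0("failure_audit_", fam, ".csv")),
                row.names = FALSE)
    }
    gl <- do.call(rbind, lapply(audits, function(a)
      if (!is.null(a)) a$guidelines))
    if (!is.null(gl) && nrow(gl))
      jsonlite::write_json(gl, file.path(ad, "guidelines.json"))
    cfg_file <- file.path(config$out_dir, "config.txt")
    writeLines(deparse(config[setdiff(names(config), "out_dir")]), cfg_file)
    files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
    manifest <- data.frame(file = list.files(config$out_dir, recursive = TRUE),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
              row.names = FALSE)
  }
  list(exp1 = exp1, exp2 = exp2, audit = audits, manifest = manifest)
}
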