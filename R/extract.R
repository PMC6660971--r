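# The 252-feature panel: 60 histogram + 10 3D shape + 3 2D shape +
# 6 sigmoid margin + 15 fractal + 44 GLCM + 44 sub-sampled GLCM + 2 ISZM +
# 5 NGTDM + 63 LoG. The roster is fixed and ordered; failed computations
# are recorded per feature, never raised.

FEATURE_FAMILIES <- c("histogram", "shape", "sigmoid", "fractal",
                      "glcm", "glcmsub", "iszm", "ngtdm", "log")

#' The fixed 252-name feature roster
#'
#' @return character vector of 252 unique, deterministically ordered names.
#' @export
feature_roster <- function() {
  c(paste("hist.whole", HIST_NAMES_19, sep = "."),
    paste("hist.pos", HIST_NAMES_14, sep = "."),
    paste("hist.inner", HIST_NAMES_9, sep = "."),
    paste("hist.outer", HIST_NAMES_9, sep = "."),
    paste("hist.delta", HIST_NAMES_9, sep = "."),
    paste("shape3d", SHAPE3D_NAMES, sep = "."),
    paste("shape2d", SHAPE2D_NAMES, sep = "."),
    sigmoid_names(),
    fractal_names(),
    paste("glcm", rep(c("whole", "inner", "outer", "delta"),
                      each = length(GLCM_MEASURES)), GLCM_MEASURES, sep = "."),
    paste("glcmsub", rep(c("whole", "inner", "outer", "delta"),
                         each = length(GLCM_MEASURES)), GLCM_MEASURES, sep = "."),
    ISZM_NAMES,
    NGTDM_NAMES,
    log_names())
}

feature_family_of <- function(names) {
  fam <- sub("\\..*$", "", names)
  fam[fam == "hist"] <- "histogram"
  fam[fam %in% c("shape3d", "shape2d")] <- "shape"
  fam
}

#' Extract the full feature panel for one case
#'
#' Runs every family on the case's ROI partition. Failures (empty ROIs,
#' degenerate texture matrices, non-converging fits) are recorded in the
#' failure slot; values of failed features are NA.
#'
#' @param case an [image_case()].
#' @param bins a [binning_spec()].
#' @param setting_id label of the extraction setting.
#' @param families subset of `FEATURE_FAMILIES` to compute (default all);
#'   the returned roster is restricted accordingly.
#' @return object of class `feature_vector`: list with `case_id`,
#'   `setting_id`, `values` (named numeric, NA = failed) and `failure`
#'   (named character reasons).
#' @export
extract_all <- function(case, bins = binning_spec(), setting_id = "default",
                        families = FEATURE_FAMILIES) {
  families <- match.arg(families, FEATURE_FAMILIES, several.ok = TRUE)
  part <- partition_roi(case)
  blocks <- list()
  if ("histogram" %in% families)
    blocks <- c(blocks, list(histogram_family(part, case$volume, bins)))
  if ("shape" %in% families) {
    b <- fb_add(new_feature_block(),
                setNames(shape3d_features(case$mask, case$spacing),
                         paste("shape3d", SHAPE3D_NAMES, sep = ".")))
    b <- fb_add(b, setNames(shape2d_features(case$mask, case$spacing),
                            paste("shape2d", SHAPE2D_NAMES, sep = ".")))
    blocks <- c(blocks, list(b))
  }
  if ("sigmoid" %in% families)
    blocks <- c(blocks, list(sigmoid_margin_features(case$volume, case$mask,
                                                     case$spacing)))
  if ("fractal" %in% families)
    blocks <- c(blocks, list(fractal_features(case$mask, case$volume)))
  if ("glcm" %in% families)
    blocks <- c(blocks, list(glcm_family(part, case$volume, bins,
                                         subsample = FALSE)))
  if ("glcmsub" %in% families)
    blocks <- c(blocks, list(glcm_family(part, case$volume, bins,
                                         subsample = TRUE)))
  if ("iszm" %in% families)
    blocks <- c(blocks, list(iszm_features(case$volume, part$whole, bins)))
  if ("ngtdm" %in% families)
    blocks <- c(blocks, list(ngtdm_features(case$volume, part$whole, bins)))
  if ("log" %in% families)
    blocks <- c(blocks, list(log_filter_features(case$volume, case$mask)))
  blk <- do.call(fb_concat, blocks)
  roster <- feature_roster()
  roster <- roster[feature_family_of(roster) %in% families]
  stopifnot(setequal(names(blk$values), roster))
  structure(list(case_id = case$case_id, setting_id = setting_id,
                 values = blk$values[roster],
                 failure = blk$failure[roster]),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  nf <- sum(x$failure != "none")
  cat(sprintf("<feature_vector> %s @ %s: %d features, %d failed\n",
              x$case_id, x$setting_id, length(x$values), nf))
  if (nf > 0) {
    tb <- table(x$failure[x$failure != "none"])
    cat("  failures:", paste(sprintf("%s (%d)", names(tb), tb),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assemble feature vectors into a feature table
#'
#' @param fvs list of `feature_vector`s sharing one setting.
#' @return data.frame with `case_id`, `setting_id` and one numeric column
#'   per roster feature (NA = failed); failure reasons in the
#'   `"failure"` attribute (character matrix, cases x features).
#' @export
feature_table <- function(fvs) {
  stopifnot(length(fvs) > 0)
  nms <- names(fvs[[1]]$values)
  vals <- do.call(rbind, lapply(fvs, function(f) unname(f$values[nms])))
  fail <- do.call(rbind, lapply(fvs, function(f) unname(f$failure[nms])))
  colnames(vals) <- nms
  colnames(fail) <- nms
  df <- data.frame(case_id = vapply(fvs, `[[`, "", "case_id"),
                   setting_id = vapply(fvs, `[[`, "", "setting_id"),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(vals, check.names = FALSE))
  rownames(fail) <- df$case_id
  attr(df, "failure") <- fail
  df
}

#' Feature column names of a feature table
#' @param tab a [feature_table()].
#' @return character vector of roster columns (identifiers excluded).
#' @export
feature_cols <- function(tab) setdiff(colnames(tab), c("case_id", "setting_id"))

#' Write / read a feature table as CSV
#'
#' Failed values serialize as empty cells plus a parallel
#' `<name>__failure` reason column.
#'
#' @param tab a [feature_table()].
#' @param path CSV path.
#' @export
write_feature_csv <- function(tab, path) {
  fail <- attr(tab, "failure")
  out <- tab
  attr(out, "failure") <- NULL
  fcols <- as.data.frame(fail, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(fcols) <- paste0(colnames(fail), "__failure")
  write.csv(cbind(out, fcols), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  fcols <- grep("__failure$", colnames(raw))
  fail <- as.matrix(raw[, fcols, drop = FALSE])
  colnames(fail) <- sub("__failure$", "", colnames(raw)[fcols])
  tab <- raw[, -fcols, drop = FALSE]
  rownames(fail) <- tab$case_id
  attr(tab, "failure") <- fail
  tab
}

#' Z-score normalization fitted on a training table
#'
#' Standardizes every feature column by its training mean and SD. Failed
#' (NA) entries stay NA; constant training features (SD = 0) are flagged
#' and excluded from the returned tables.
#'
#' @param train_table,apply_table feature tables; `apply_table` (optional)
#'   is standardized with the training parameters.
#' @return list with `train`, `apply` (or NULL), `center`, `scale` and
#'   `constant` (names of excluded constant features).
#' @export
zscore_normalize <- function(train_table, apply_table = NULL) {
  fc <- feature_cols(train_table)
  ctr <- vapply(train_table[fc], function(x) mean(x, na.rm = TRUE), numeric(1))
  scl <- vapply(train_table[fc], function(x) sd(x, na.rm = TRUE), numeric(1))
  n_ok <- vapply(train_table[fc], function(x) sum(!is.na(x)), numeric(1))
  constant <- fc[!is.na(scl) & (scl == 0 | n_ok < 2)]
  if (length(constant))
    warning(sprintf("%d constant feature(s) excluded from normalization: %s",
                    length(constant),
                    paste(head(constant, 5), collapse = ", ")))
  keep <- setdiff(fc, constant)
  norm <- function(tab) {
    out <- tab[c("case_id", "setting_id", keep)]
    for (f in keep) out[[f]] <- (tab[[f]] - ctr[f]) / scl[f]
    fl <- attr(tab, "failure")
    if (!is.null(fl)) attr(out, "failure") <- fl[, keep, drop = FALSE]
    out
  }
  list(train = norm(train_table),
       apply = if (!is.null(apply_table)) norm(apply_table),
       center = ctr[keep], scale = scl[keep], constant = constant)
}

#' Extract a feature table for a list of cases
#'
#' @param cases list of [image_case()]s (or a `radrep_cohort`).
#' @param bins a [binning_spec()].
#' @param setting_id setting label.
#' @param resample_to optional isotropic target spacing (mm); cases whose
#'   nodule vanishes under resampling get all-failed rows (`empty_roi`).
#' @param families families to compute.
#' @return a [feature_table()].
#' @export
extract_table <- function(cases, bins = binning_spec(),
                          setting_id = "default", resample_to = NULL,
                          families = FEATURE_FAMILIES) {
  if (inherits(cases, "radrep_cohort")) cases <- cases$cases
  roster <- feature_roster()
  roster <- roster[feature_family_of(roster) %in% families]
  fvs <- lapply(cases, function(cs) {
    if (!is.null(resample_to)) {
      id <- cs$case_id
      cs <- tryCatch(resample_isotropic(cs, resample_to),
                     error = function(e) NULL)
      if (is.null(cs)) {
        return(structure(list(case_id = id, setting_id = setting_id,
                              values = setNames(rep(NA_real_, length(roster)), roster),
                              failure = setNames(rep("empty_roi", length(roster)), roster)),
                         class = "feature_vector"))
      }
    }
    extract_all(cs, bins, setting_id, families = families)
  })
  feature_table(fvs)
}
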