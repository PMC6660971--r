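#' Construct an image case
#'
#' Bundles one CT-like volume, its binary nodule mask, the voxel spacing and
#' the nodule status into the unit of processing used throughout the package.
#'
#' @param case_id character scalar identifier.
#' @param volume 3D numeric array of intensities in Hounsfield units (HU).
#' @param mask 3D array on the same grid; voxels > 0 are nodule.
#' @param spacing numeric length-3 voxel spacing in mm (axis 3 = slice axis).
#' @param status one of `"benign"`, `"malignant"`, `"unknown"`.
#' @return An object of class `image_case`.
#' @export
image_case <- function(case_id, volume, mask, spacing,
                       status = c("unknown", "benign", "malignant")) {
  status <- match.arg(status)
  if (!identical(dim(volume), dim(mask)))
    stop("volume and mask must share grid shape", call. = FALSE)
  if (length(dim(volume)) != 3L)
    stop("volume must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm)", call. = FALSE)
  m <- array(mask > 0, dim(mask))
  if (!any(m)) stop("empty ROI: mask has no foreground voxel", call. = FALSE)
  structure(
    list(case_id = as.character(case_id), volume = volume, mask = m,
         spacing = spacing, status = status),
    class = "image_case")
}

#' @export
print.image_case <- function(x, ...) {
  cat(sprintf("<image_case> %s  grid %s  spacing %s mm  |ROI| = %d voxels  status: %s\n",
              x$case_id, paste(dim(x$volume), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              sum(x$mask), x$status))
  invisible(x)
}

nrrd_type_map <- c("unsigned char" = "uchar", "uchar" = "uchar",
                   "uint8" = "uchar", "uint8_t" = "uchar",
                   "double" = "double", "float" = "float",
                   "short" = "short", "signed short" = "short",
                   "int" = "int", "signed int" = "int")

#' Write a 3D array as a NRRD file
#'
#' Minimal NRRD0004 writer (raw encoding, little endian) storing voxel
#' spacing in the header. Volumes are written as `double`, masks as
#' `unsigned char` in {0, 1}.
#'
#' @param a 3D array.
#' @param path output path (`.nrrd`).
#' @param spacing voxel spacing in mm.
#' @param type `"double"` or `"uchar"`.
#' @export
write_nrrd <- function(a, path, spacing, type = c("double", "uchar")) {
  type <- match.arg(type)
  dm <- dim(a)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# radrep minimal NRRD",
    sprintf("type: %s", if (type == "uchar") "unsigned char" else "double"),
    "dimension: 3",
    sprintf("sizes: %d %d %d", dm[1], dm[2], dm[3]),
    sprintf("spacings: %.10g %.10g %.10g", spacing[1], spacing[2], spacing[3]),
    "encoding: raw",
    "endian: little",
    "", "")                      # blank line terminates the header
  writeChar(paste0(hdr, collapse = "\n"), con, eos = NULL)
  if (type == "uchar") {
    writeBin(as.raw(as.integer(a > 0)), con)
  } else {
    writeBin(as.double(a), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read a NRRD file written by [write_nrrd()] (or any raw-encoded,
#' little-endian 3D NRRD with per-axis spacings)
#'
#' @param path path to a `.nrrd` file.
#' @return list with `data` (3D array) and `spacing` (mm).
#' @export
read_nrrd <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  # header ends at the first blank line
  nl <- which(raw_all == as.raw(10L))
  split_at <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L) { split_at <- p; break }
    prev <- p
  }
  if (is.na(split_at)) stop("truncated NRRD header", call. = FALSE)
  hdr <- strsplit(rawToChar(raw_all[seq_len(split_at - 1L)]), "\n")[[1]]
  body <- raw_all[(split_at + 1L):length(raw_all)]
  field <- function(key) {
    ln <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^", key, ": "), "", ln[1])
  }
  type <- nrrd_type_map[[field("type")]]
  if (is.null(type)) stop("unsupported NRRD type", call. = FALSE)
  sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  enc <- field("encoding")
  if (!identical(enc, "raw")) stop("only raw NRRD encoding supported", call. = FALSE)
  spacing <- field("spacings")
  if (is.null(spacing)) {
    sd <- field("space directions")
    if (!is.null(sd)) {
      vecs <- regmatches(sd, gregexpr("\\(([^)]*)\\)", sd))[[1]]
      spacing <- vapply(vecs, function(v) {
        nums <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
        sqrt(sum(nums^2))
      }, numeric(1))
    } else spacing <- rep(1, length(sizes))
  } else spacing <- as.numeric(strsplit(spacing, "\\s+")[[1]])
  n <- prod(sizes)
  data <- switch(type,
    uchar = as.numeric(readBin(body, "integer", n = n, size = 1, signed = FALSE)),
    short = as.numeric(readBin(body, "integer", n = n, size = 2, endian = "little")),
    int = as.numeric(readBin(body, "integer", n = n, size = 4, endian = "little")),
    float = readBin(body, "double", n = n, size = 4, endian = "little"),
    double = readBin(body, "double", n = n, size = 8, endian = "little"))
  if (length(data) != n) stop("truncated NRRD data", call. = FALSE)
  dim(data) <- sizes
  list(data = data, spacing = as.numeric(spacing))
}

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

read_volume <- function(path) {
  if (is_nifti_path(path)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1:3]
    arr <- as.array(img)
    arr <- array(as.double(arr), dim(arr)[1:3])
    list(data = arr, spacing = as.numeric(sp))
  } else {
    read_nrrd(path)
  }
}

write_volume <- function(a, path, spacing, type = "double") {
  if (is_nifti_path(path)) {
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
    invisible(path)
  } else {
    write_nrrd(a, path, spacing, type = type)
  }
}

#' Load one case from image and mask files
#'
#' Reads NRRD (default) or NIfTI-1 volumes, checks that the grids and
#' spacings agree, binarizes the mask at > 0 and returns an [image_case()].
#'
#' @param image_path,mask_path paths to the intensity volume and mask.
#' @param status nodule status label.
#' @param case_id identifier; defaults to the image file stem.
#' @export
load_case <- function(image_path, mask_path, status = "unknown",
                      case_id = NULL) {
  img <- read_volume(image_path)
  msk <- read_volume(mask_path)
  if (!identical(dim(img$data), dim(msk$data)))
    stop("format error: image and mask grids differ", call. = FALSE)
  if (max(abs(img$spacing - msk$spacing)) > 1e-4)
    stop("format error: image and mask spacing differ", call. = FALSE)
  if (is.null(case_id))
    case_id <- sub("\\.(nrrd|nii|nii\\.gz)$", "", basename(image_path),
                   ignore.case = TRUE)
  image_case(case_id, img$data, msk$data, img$spacing, status = status)
}

#' Write a case to an image/mask file pair
#'
#' @param case an [image_case()].
#' @param dir output directory.
#' @param format `"nrrd"` (default) or `"nifti"`.
#' @return character vector of the two paths written.
#' @export
write_case <- function(case, dir, format = c("nrrd", "nifti")) {
  format <- match.arg(format)
  ext <- if (format == "nrrd") ".nrrd" else ".nii.gz"
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ip <- file.path(dir, paste0(case$case_id, "_img", ext))
  mp <- file.path(dir, paste0(case$case_id, "_msk", ext))
  write_volume(case$volume, ip, case$spacing, type = "double")
  write_volume(case$mask * 1L, mp, case$spacing, type = "uchar")
  c(image = ip, mask = mp)
}
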