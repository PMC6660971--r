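# Synthetic CT nodule cohorts. Intensities emulate thoracic CT: lung
# parenchyma near -850 HU, solid nodule tissue near +20 HU, pure
# ground-glass near -600 HU, with a sigmoid density transition at the
# margin and spatially correlated texture inside the nodule. The generator
# supplies ground truth for every parameter so that downstream selection
# stages can be checked against planted effects.

HU_LUNG  <- -850
HU_SOLID <- 20
HU_GGO   <- -600

#' Specify one synthetic nodule
#'
#' @param equivalent_diameter nodule diameter in mm (must be <= 20 mm;
#'   screening-relevant nodules are sub-2 cm).
#' @param shape_class `"sphere"`, `"ellipsoid"` or `"lobulated"` (sphere with
#'   a low-order spherical-harmonic radial perturbation).
#' @param ggo_fraction fraction in \[0, 1\] of ground-glass density; 0 gives a
#'   solid nodule core near +20 HU, 1 a pure GGO core near -600 HU.
#' @param core_intensity core HU; defaults to the GGO/solid interpolation.
#' @param margin_width sigmoid transition width of the margin in mm
#'   (0 = step edge).
#' @param texture_amplitude standard deviation in HU of the spatially
#'   correlated intensity texture inside the nodule.
#' @param texture_scale correlation length of the texture in mm.
#' @param status nodule status label.
#' @param center physical center in mm, or `NULL` for the grid center.
#' @return A list of class `nodule_spec`.
#' @export
nodule_spec <- function(equivalent_diameter,
                        shape_class = c("sphere", "ellipsoid", "lobulated"),
                        ggo_fraction = 0,
                        core_intensity = NULL,
                        margin_width = 1.5,
                        texture_amplitude = 40,
                        texture_scale = 1.5,
                        status = c("unknown", "benign", "malignant"),
                        center = NULL) {
  shape_class <- match.arg(shape_class)
  status <- match.arg(status)
  if (equivalent_diameter > 20)
    stop("equivalent_diameter must be <= 20 mm", call. = FALSE)
  if (equivalent_diameter <= 0)
    stop("equivalent_diameter must be positive", call. = FALSE)
  if (ggo_fraction < 0 || ggo_fraction > 1)
    stop("ggo_fraction must lie in [0, 1]", call. = FALSE)
  if (margin_width < 0 || texture_amplitude < 0)
    stop("margin_width and texture_amplitude must be >= 0", call. = FALSE)
  if (is.null(core_intensity))
    core_intensity <- (1 - ggo_fraction) * HU_SOLID + ggo_fraction * HU_GGO
  structure(list(
    equivalent_diameter = equivalent_diameter,
    shape_class = shape_class,
    ggo_fraction = ggo_fraction,
    core_intensity = core_intensity,
    margin_width = margin_width,
    texture_amplitude = texture_amplitude,
    texture_scale = texture_scale,
    status = status,
    center = center), class = "nodule_spec")
}

# Directional radius factor of the nodule surface. Returns a function of
# unit direction vectors (n x 3 matrix) giving the local radius in mm.
radius_function <- function(spec, shape_params) {
  R <- spec$equivalent_diameter / 2
  switch(spec$shape_class,
    sphere = function(u) rep(R, nrow(u)),
    ellipsoid = {
      ax <- R * shape_params$axis_ratios
      function(u) {
        1 / sqrt((u[, 1] / ax[1])^2 + (u[, 2] / ax[2])^2 + (u[, 3] / ax[3])^2)
      }
    },
    lobulated = {
      amp <- shape_params$harmonic_amp
      function(u) {
        ct <- u[, 3]
        st2 <- pmax(0, 1 - ct^2)
        phi <- atan2(u[, 2], u[, 1])
        pert <- amp[1] * (3 * ct^2 - 1) / 2 +
          amp[2] * st2 * cos(2 * phi) +
          amp[3] * st2 * sqrt(st2) * cos(3 * phi)
        R * (1 + pert)
      }
    })
}

# Internal shape randomness drawn from the active RNG stream.
draw_shape_params <- function(spec) {
  switch(spec$shape_class,
    sphere = list(),
    ellipsoid = {
      r <- c(1, runif(1, 0.65, 0.95), runif(1, 0.55, 0.9))
      list(axis_ratios = r / prod(r)^(1 / 3))   # volume-preserving
    },
    lobulated = list(harmonic_amp = runif(3, -0.12, 0.12)))
}

analytic_volume <- function(spec, shape_params) {
  R <- spec$equivalent_diameter / 2
  base <- 4 / 3 * pi * R^3
  if (spec$shape_class == "ellipsoid") {
    base * prod(shape_params$axis_ratios)       # == base (ratios normalized)
  } else base
}

#' Generate one synthetic CT nodule case
#'
#' Rasterizes the nodule of `spec` onto a voxel grid: background lung
#' parenchyma at -850 HU plus Gaussian noise, nodule interior at the core
#' intensity modulated by correlated texture, and a sigmoid intensity
#' transition of width `margin_width` in signed distance to the surface.
#' The returned mask is the exact support (signed distance <= 0).
#'
#' @param spec a [nodule_spec()].
#' @param spacing voxel spacing in mm (length 3; axis 3 = slice axis).
#' @param grid_shape grid dimensions, or `NULL` to fit the nodule with a
#'   `grid_margin` mm margin.
#' @param noise_sd additive Gaussian noise SD in HU.
#' @param seed optional integer; when given, generation is wrapped in a
#'   local RNG state so the global stream is untouched.
#' @param grid_margin mm of background retained around the nodule.
#' @param case_id identifier.
#' @return An [image_case()] with attribute `"truth"` recording the spec,
#'   internal shape parameters and analytic volume.
#' @export
generate_case <- function(spec, spacing, grid_shape = NULL, noise_sd = 20,
                          seed = NULL, grid_margin = 6, case_id = "case") {
  if (!is.null(seed))
    return(withr::with_seed(seed,
      generate_case(spec, spacing, grid_shape, noise_sd, NULL,
                    grid_margin, case_id)))
  spacing <- as.numeric(spacing)
  d <- spec$equivalent_diameter
  need <- d * 1.25 + 2 * max(grid_margin, 5)   # lobulation headroom
  if (is.null(grid_shape)) {
    grid_shape <- pmax(4L, as.integer(ceiling(need / spacing)))
  } else if (any(grid_shape * spacing < d + 2 * 5)) {
    stop("sizing error: grid cannot contain the nodule with a 5 mm margin",
         call. = FALSE)
  }
  shape_params <- draw_shape_params(spec)
  ctr <- spec$center
  if (is.null(ctr)) ctr <- grid_shape * spacing / 2
  # physical voxel-center coordinates
  gx <- (seq_len(grid_shape[1]) - 0.5) * spacing[1]
  gy <- (seq_len(grid_shape[2]) - 0.5) * spacing[2]
  gz <- (seq_len(grid_shape[3]) - 0.5) * spacing[3]
  X <- array(gx, grid_shape) - ctr[1]
  Y <- array(rep(gy, each = grid_shape[1]), grid_shape) - ctr[2]
  Z <- array(rep(gz, each = grid_shape[1] * grid_shape[2]), grid_shape) - ctr[3]
  r <- sqrt(X^2 + Y^2 + Z^2)
  u <- cbind(as.vector(X), as.vector(Y), as.vector(Z)) / pmax(as.vector(r), 1e-9)
  rad <- radius_function(spec, shape_params)(u)
  sdist <- r - array(rad, grid_shape)          # signed distance, < 0 inside
  mask <- sdist <= 0
  if (!any(mask)) stop("sizing error: nodule support empty on this grid",
                       call. = FALSE)
  w <- spec$margin_width / 4                   # logistic scale; width ~ central 76%
  inside_w <- if (w <= 1e-9) mask * 1 else 1 / (1 + exp(sdist / w))
  tex <- 0
  if (spec$texture_amplitude > 0) {
    wn <- array(rnorm(prod(grid_shape)), grid_shape)
    sm <- gauss_smooth3(wn, spec$texture_scale / spacing)
    s <- sd(as.vector(sm))
    if (s > 0) tex <- sm / s * spec$texture_amplitude
  }
  vol <- HU_LUNG + (spec$core_intensity + tex - HU_LUNG) * inside_w
  if (noise_sd > 0) vol <- vol + array(rnorm(prod(grid_shape), 0, noise_sd),
                                       grid_shape)
  case <- image_case(case_id, vol, mask, spacing, status = spec$status)
  attr(case, "truth") <- list(spec = spec, shape_params = shape_params,
                              analytic_volume = analytic_volume(spec, shape_params),
                              mask_volume = sum(mask) * prod(spacing))
  case
}

#' Configure a synthetic cohort
#'
#' Defaults mirror sub-2 cm screening nodules on thoracic CT: in-plane
#' spacing 0.49–0.9 mm, slice thickness 1–2.5 mm, diameters centred near
#' 11 mm, and a sub-population of very small nodules (3–5.5 mm) that makes
#' neighbourhood-based texture families fail downstream. The
#' `effect_profile` lists malignant-minus-benign offsets for the planted
#' class differences.
#'
#' @param n_cases number of cases (>= 2).
#' @param class_balance fraction malignant.
#' @param spacing_range_inplane,spacing_range_slice per-case spacing draws (mm).
#' @param diameter_mean,diameter_sd,diameter_range regular-nodule diameter
#'   distribution (truncated normal, mm).
#' @param small_nodule_fraction fraction of cases with diameters drawn from
#'   `small_diameter_range` (mm), planted to trigger texture failures.
#' @param small_diameter_range diameter range of the small sub-population.
#' @param effect_profile named list of malignant offsets:
#'   `size` (mm), `core_intensity` (HU), `margin_width` (mm),
#'   `texture_amplitude` (HU).
#' @param ggo_fraction_range per-case uniform draw of the GGO fraction.
#' @param margin_width_base,texture_amplitude_base benign-class baselines.
#' @param noise_sd additive image noise SD (HU).
#' @param rng_seed integer seed; identical configs reproduce bit-identical
#'   cohorts.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 60,
                          class_balance = 0.5,
                          spacing_range_inplane = c(0.49, 0.9),
                          spacing_range_slice = c(1.0, 2.5),
                          diameter_mean = 11, diameter_sd = 3,
                          diameter_range = c(6, 19),
                          small_nodule_fraction = 0,
                          small_diameter_range = c(3, 5.5),
                          effect_profile = list(size = 3,
                                                core_intensity = 80,
                                                margin_width = -0.8,
                                                texture_amplitude = 40),
                          ggo_fraction_range = c(0, 0.4),
                          margin_width_base = 1.6,
                          texture_amplitude_base = 35,
                          noise_sd = 20,
                          rng_seed = 1L) {
  stopifnot(n_cases >= 2, class_balance >= 0, class_balance <= 1,
            small_nodule_fraction >= 0, small_nodule_fraction <= 1)
  if (spacing_range_inplane[1] < 0.49 - 1e-9 || spacing_range_inplane[2] > 0.9 + 1e-9)
    warning("in-plane spacing outside the default 0.49-0.9 mm envelope")
  if (spacing_range_slice[1] < 0.625 - 1e-9 || spacing_range_slice[2] > 5 + 1e-9)
    warning("slice spacing outside the default 0.625-5 mm envelope")
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic cohort with its ground-truth table
#'
#' @param config a [cohort_config()].
#' @return list of class `radrep_cohort` with elements `cases` (list of
#'   [image_case()]) and `truth` (data.frame of every planted parameter).
#' @export
generate_cohort <- function(config) {
  n <- config$n_cases
  n_mal <- round(n * config$class_balance)
  if (config$class_balance > 0 && config$class_balance < 1 &&
      (n_mal == 0L || n_mal == n))
    stop("config error: both classes must be representable at this n_cases",
         call. = FALSE)
  withr::with_seed(config$rng_seed, {
    status <- rep("benign", n)
    status[sample.int(n, n_mal)] <- "malignant"
    n_small <- round(n * config$small_nodule_fraction)
    small <- rep(FALSE, n)
    if (n_small > 0) small[sample.int(n, n_small)] <- TRUE
    eff <- config$effect_profile
    shapes <- c("sphere", "ellipsoid", "lobulated")
    cases <- vector("list", n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      mal <- status[i] == "malignant"
      if (small[i]) {
        d <- runif(1, config$small_diameter_range[1], config$small_diameter_range[2])
      } else {
        mu <- config$diameter_mean + if (mal) eff$size else 0
        repeat {
          d <- rnorm(1, mu, config$diameter_sd)
          if (d >= config$diameter_range[1] && d <= config$diameter_range[2]) break
        }
      }
      ggo <- runif(1, config$ggo_fraction_range[1], config$ggo_fraction_range[2])
      core <- (1 - ggo) * HU_SOLID + ggo * HU_GGO + if (mal) eff$core_intensity else 0
      mw <- max(0, config$margin_width_base + if (mal) eff$margin_width else 0)
      ta <- max(0, config$texture_amplitude_base + if (mal) eff$texture_amplitude else 0)
      sp_in <- runif(1, config$spacing_range_inplane[1], config$spacing_range_inplane[2])
      sp_sl <- runif(1, config$spacing_range_slice[1], config$spacing_range_slice[2])
      spacing <- c(sp_in, sp_in, sp_sl)
      spec <- nodule_spec(d, shape_class = shapes[1 + (i - 1) %% 3],
                          ggo_fraction = ggo, core_intensity = core,
                          margin_width = mw, texture_amplitude = ta,
                          status = if (mal) "malignant" else "benign")
      id <- sprintf("case%03d", i)
      cases[[i]] <- generate_case(spec, spacing, noise_sd = config$noise_sd,
                                  case_id = id)
      tr <- attr(cases[[i]], "truth")
      rows[[i]] <- data.frame(
        case_id = id, status = spec$status,
        equivalent_diameter = d, shape_class = spec$shape_class,
        core_intensity = core, ggo_fraction = ggo,
        margin_width = mw, texture_amplitude = ta,
        spacing_inplane = sp_in, spacing_slice = sp_sl,
        small_nodule = small[i],
        analytic_volume = tr$analytic_volume,
        mask_volume = tr$mask_volume,
        stringsAsFactors = FALSE)
    }
    structure(list(cases = cases, truth = do.call(rbind, rows),
                   config = config),
              class = "radrep_cohort")
  })
}

#' @export
print.radrep_cohort <- function(x, ...) {
  tb <- table(x$truth$status)
  cat(sprintf("<radrep_cohort> %d cases (%s), %d flagged small, seed %d\n",
              nrow(x$truth),
              paste(sprintf("%s: %d", names(tb), tb), collapse = ", "),
              sum(x$truth$small_nodule), x$config$rng_seed))
  invisible(x)
}

#' Write a cohort to disk (volumes, masks and truth table)
#'
#' @param cohort a `radrep_cohort`.
#' @param dir output directory.
#' @param format `"nrrd"` (default) or `"nifti"`.
#' @export
write_cohort <- function(cohort, dir, format = c("nrrd", "nifti")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (cs in cohort$cases) write_case(cs, dir, format = format)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
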