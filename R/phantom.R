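# Synthetic phantom-image generator.
#
# Emulates top-down NIR fluorescence images of a 3D-printed tumor inclusion
# embedded in tissue-mimicking bulk material. The forward model is
# deliberately simple and fully testable: emission proportional to fluorophore
# concentration, single-exponential depth attenuation with the
# diffusion-approximation mu_eff, a smooth multiplicative illumination field,
# Gaussian blur for system/diffusion spread, a Poisson+Gaussian sensor model,
# and per-system quantization.

#' Parametric ellipse tumor geometry
#'
#' @param center_mm Tumor center `c(row_mm, col_mm)` in mm from the image
#'   top-left corner.
#' @param semi_axes_mm Ellipse semi-axes `c(a, b)` in mm (row, col before
#'   rotation).
#' @param rotation_deg Counter-clockwise rotation in degrees.
#' @return A tumor-geometry descriptor for [phantom_spec()].
#' @export
tumor_ellipse <- function(center_mm, semi_axes_mm, rotation_deg = 0) {
  check_number(center_mm, "center_mm", len = 2L)
  check_number(semi_axes_mm, "semi_axes_mm", min = 0, strict_min = TRUE, len = 2L)
  check_number(rotation_deg, "rotation_deg")
  structure(list(type = "ellipse", center_mm = center_mm,
                 semi_axes_mm = semi_axes_mm, rotation_deg = rotation_deg),
            class = "tumor_geometry")
}

#' Tumor geometry from a binary raster mask
#'
#' Accepts a logical matrix or a path to a binary PNG (nonzero = tumor), e.g.
#' an anatomical outline exported from segmentation software.
#'
#' @param mask Logical matrix, or path to a binary PNG.
#' @return A tumor-geometry descriptor for [phantom_spec()].
#' @export
tumor_raster <- function(mask) {
  if (is.character(mask)) {
    m <- png::readPNG(mask)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    mask <- as.matrix(m) > 0
  }
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop_nir("invalid_parameter", "mask must be a logical matrix or a PNG path")
  }
  structure(list(type = "raster", mask = mask), class = "tumor_geometry")
}

#' Ground-truth description of a simulated phantom
#'
#' The defaults reproduce the breast-model study condition: a 28.5 x 21.0 mm
#' tumor inclusion 2.2 mm below the imaging plane in normal-breast bulk
#' material, 1 uM ICG-equivalent fluorophore in the tumor and 0.03 uM in the
#' bulk, imaged by a 16-bit research system.
#'
#' @param tumor A [tumor_ellipse()] or [tumor_raster()] geometry.
#' @param tumor_depth Distance from tumor to the imaging plane, mm.
#' @param c_tumor,c_background Fluorophore concentrations, uM (>= 0).
#' @param optics Bulk [optical_properties()]; governs depth attenuation.
#' @param blur_sigma Gaussian blur sigma in mm (system + diffusion spread).
#' @param field_inhomogeneity_amplitude Peak relative amplitude of the smooth
#'   multiplicative illumination field, in `[0, 1)`; the field has mean 1.
#' @param noise A [noise_model()].
#' @param system A [system_profile()].
#' @param image_shape Raster size `c(rows, cols)` in pixels.
#' @param px_per_mm Spatial calibration, pixels per mm.
#' @param footprint Optional logical matrix marking the phantom footprint;
#'   emission is zero outside it. Default: the full image.
#' @param seed Integer seed; the same spec yields bit-identical images.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(tumor = tumor_ellipse(c(25.6, 25.6), c(14.25, 10.5)),
                         tumor_depth = 2.2,
                         c_tumor = 1, c_background = 0.03,
                         optics = optics_presets("breast_normal"),
                         blur_sigma = 0.5,
                         field_inhomogeneity_amplitude = 0.05,
                         noise = noise_model(),
                         system = system_profile("research"),
                         image_shape = c(256L, 256L),
                         px_per_mm = 5,
                         footprint = NULL,
                         seed = 1L) {
  stopifnot(inherits(tumor, "tumor_geometry"),
            inherits(optics, "optical_properties"),
            inherits(noise, "noise_model"),
            inherits(system, "system_profile"))
  check_number(c_tumor, "c_tumor", min = 0)
  check_number(c_background, "c_background", min = 0)
  check_number(tumor_depth, "tumor_depth", min = 0)
  check_number(blur_sigma, "blur_sigma", min = 0)
  check_number(field_inhomogeneity_amplitude, "field_inhomogeneity_amplitude", min = 0)
  if (field_inhomogeneity_amplitude >= 1) {
    stop_nir("invalid_parameter", "field_inhomogeneity_amplitude must be < 1")
  }
  check_number(px_per_mm, "px_per_mm", min = 0, strict_min = TRUE)
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 8L)) {
    stop_nir("invalid_parameter", "image_shape must be c(rows, cols), each >= 8")
  }
  if (!is.null(footprint)) {
    stopifnot(is.logical(footprint), all(dim(footprint) == image_shape))
  }
  structure(list(tumor = tumor, tumor_depth = tumor_depth,
                 c_tumor = c_tumor, c_background = c_background,
                 optics = optics, blur_sigma = blur_sigma,
                 field_inhomogeneity_amplitude = field_inhomogeneity_amplitude,
                 noise = noise, system = system,
                 image_shape = image_shape, px_per_mm = px_per_mm,
                 footprint = footprint, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("phantom spec: c_T = %g uM, c_B = %g uM, depth %g mm, ",
                     "%d x %d px @ %g px/mm, system '%s', seed %d\n"),
              x$c_tumor, x$c_background, x$tumor_depth,
              x$image_shape[1], x$image_shape[2], x$px_per_mm,
              x$system$name, x$seed))
  invisible(x)
}

# Rasterize a tumor geometry; pixel centers at (i - 0.5)/px_per_mm mm.
rasterize_tumor <- function(tumor, image_shape, px_per_mm) {
  if (tumor$type == "raster") {
    if (!all(dim(tumor$mask) == image_shape)) {
      stop_nir("geometry", "tumor raster %d x %d does not match image %d x %d",
               nrow(tumor$mask), ncol(tumor$mask), image_shape[1], image_shape[2])
    }
    return(tumor$mask)
  }
  rows_mm <- (seq_len(image_shape[1]) - 0.5) / px_per_mm
  cols_mm <- (seq_len(image_shape[2]) - 0.5) / px_per_mm
  th <- tumor$rotation_deg * pi / 180
  a <- tumor$semi_axes_mm[1]; b <- tumor$semi_axes_mm[2]
  dr <- outer(rows_mm - tumor$center_mm[1], rep(1, image_shape[2]))
  dc <- outer(rep(1, image_shape[1]), cols_mm - tumor$center_mm[2])
  u <- cos(th) * dr + sin(th) * dc
  v <- -sin(th) * dr + cos(th) * dc
  mask <- (u / a)^2 + (v / b)^2 <= 1
  # geometry must fit inside the frame
  ext_mm <- c(image_shape[1], image_shape[2]) / px_per_mm
  reach <- max(a, b)
  if (any(tumor$center_mm - reach < 0) || any(tumor$center_mm + reach > ext_mm)) {
    stop_nir("geometry", "tumor ellipse extends outside the %g x %g mm image", ext_mm[1], ext_mm[2])
  }
  if (!any(mask)) stop_nir("geometry", "tumor mask rasterized to zero pixels")
  mask
}

# Smooth zero-mean multiplicative illumination field with peak amplitude
# `amp`: a broad Gaussian beam profile (central hot spot, as produced by
# beam-expanded laser illumination) whose center is randomly jittered by up
# to 10% of the frame, recentred so its mean over the frame is exactly zero.
illumination_field <- function(image_shape, amp) {
  if (amp == 0) return(matrix(1, image_shape[1], image_shape[2]))
  jit <- stats::runif(2, -0.1, 0.1)
  ctr <- (image_shape + 1) / 2 + jit * image_shape
  w <- 0.5 * min(image_shape)
  dr <- outer(seq_len(image_shape[1]) - ctr[1], rep(1, image_shape[2]))
  dc <- outer(rep(1, image_shape[1]), seq_len(image_shape[2]) - ctr[2])
  g <- exp(-(dr^2 + dc^2) / (2 * w^2))
  g <- g - mean(g)
  m <- max(abs(g))
  if (m > 0) g <- g / m
  1 + amp * g
}

gaussian_blur <- function(x, sigma_px) {
  if (sigma_px <= 0) return(x)
  size <- 2L * as.integer(ceiling(3 * sigma_px)) + 1L
  kern <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma_px)
  kern <- kern / sum(kern)
  as.matrix(EBImage::filter2(x, kern, boundary = "replicate"))
}

quantize <- function(x, system) {
  levels <- 2^system$bit_depth - 1
  if (system$auto_gain) {
    mx <- max(x)
    scale <- if (mx > 0) levels / mx else 0
  } else {
    scale <- levels  # fixed gain: 1.0 intensity unit is full scale
  }
  dn <- round(x * scale)
  pmin(pmax(dn, 0), levels)
}

#' Generate a synthetic phantom image with ground truth
#'
#' Runs the forward model for one [phantom_spec()]: emission
#' `c_tumor * exp(-mu_eff * tumor_depth)` on tumor pixels and `c_background`
#' on the rest of the phantom footprint; multiplication by a smooth
#' illumination field of mean 1; Gaussian blur; Poisson/Gaussian sensor noise;
#' quantization per the system profile (auto-gain scales the frame maximum to
#' full scale). The same seed yields bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements:
#'   \describe{
#'     \item{image}{[calibrated_image()] (quantized then unit-normalized).}
#'     \item{truth}{`ground_truth` list: `tumor_mask`; `background_mask` (the
#'       footprint minus the tumor and a 2-pixel dilation ring, so blur does
#'       not contaminate background statistics); `true_ratio`
#'       (`c_tumor * exp(-mu_eff * depth) / c_background`, `NA` with
#'       `ratio_defined = FALSE` when `c_background = 0`); `prequant` (the
#'       noiseless, unquantized emission field for validation).}
#'   }
#' @examples
#' out <- generate_phantom_image(phantom_spec(seed = 7))
#' out$image
#' out$truth$true_ratio
#' @export
generate_phantom_image <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  tumor <- rasterize_tumor(spec$tumor, spec$image_shape, spec$px_per_mm)
  footprint <- spec$footprint %||% matrix(TRUE, spec$image_shape[1], spec$image_shape[2])
  mu_eff <- effective_attenuation(spec$optics)
  emission <- matrix(0, spec$image_shape[1], spec$image_shape[2])
  emission[footprint] <- spec$c_background
  emission[tumor & footprint] <- spec$c_tumor * exp(-mu_eff * spec$tumor_depth)
  ideal <- emission  # pre-illumination, pre-blur field

  out <- with_seed(spec$seed, {
    x <- emission * illumination_field(spec$image_shape,
                                       spec$field_inhomogeneity_amplitude)
    x <- gaussian_blur(x, spec$blur_sigma * spec$px_per_mm)
    prequant <- x
    if (spec$noise$shot_noise_gain > 0) {
      x <- matrix(stats::rpois(length(x), pmax(x, 0) * spec$noise$shot_noise_gain) /
                    spec$noise$shot_noise_gain,
                  nrow(x), ncol(x))
    }
    if (spec$noise$read_noise_sd > 0) {
      x <- x + matrix(stats::rnorm(length(x), 0, spec$noise$read_noise_sd),
                      nrow(x), ncol(x))
    }
    x <- pmax(x, 0)
    list(dn = quantize(x, spec$system), prequant = prequant)
  })

  ring <- EBImage::dilate(EBImage::Image(tumor * 1), EBImage::makeBrush(5, "disc")) > 0
  background_mask <- footprint & !as.matrix(ring)
  ratio_defined <- spec$c_background > 0
  truth <- structure(list(
    tumor_mask = tumor,
    background_mask = background_mask,
    true_ratio = if (ratio_defined)
      spec$c_tumor * exp(-mu_eff * spec$tumor_depth) / spec$c_background else NA_real_,
    ratio_defined = ratio_defined,
    mu_eff = mu_eff,
    prequant = out$prequant,
    ideal = ideal
  ), class = "ground_truth")

  image <- calibrated_image(out$dn, px_per_mm = spec$px_per_mm,
                            source_bit_depth = spec$system$bit_depth,
                            provenance = list(system = spec$system$name,
                                              simulated = TRUE,
                                              seed = spec$seed))
  list(image = image, truth = truth)
}

#' Generate a replicated concentration series
#'
#' One image per (tumor concentration, replicate). Replicates of the same
#' concentration differ only by noise realization and a small random
#' sub-pixel jitter of the tumor position, emulating removing and
#' repositioning the phantom between acquisitions.
#'
#' @param base_spec A [phantom_spec()] whose `c_tumor` is overridden.
#' @param concentrations Tumor concentrations in uM (default the study series
#'   0.03, 0.1, 0.3, 1).
#' @param replicates Replicates per concentration (default 3).
#' @param seed Series seed (default `base_spec$seed`).
#' @param jitter_px Max absolute sub-pixel positional jitter per axis in
#'   pixels (default 0.5; 0 disables). Ignored for raster tumor geometries.
#' @return A list with one element per image: `list(image, truth, condition)`
#'   where `condition` holds `c_tumor`, `c_background` and `replicate`.
#' @export
generate_concentration_series <- function(base_spec,
                                          concentrations = c(0.03, 0.1, 0.3, 1),
                                          replicates = 3L,
                                          seed = base_spec$seed,
                                          jitter_px = 0.5) {
  stopifnot(inherits(base_spec, "phantom_spec"))
  if (length(concentrations) == 0L) {
    stop_nir("invalid_parameter", "concentrations must be nonempty")
  }
  check_number(concentrations, "concentrations", min = 0, len = length(concentrations))
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop_nir("invalid_parameter", "replicates must be >= 1")
  }
  check_number(jitter_px, "jitter_px", min = 0)
  n <- length(concentrations) * replicates
  plan <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max, n),
    jitter = matrix(stats::runif(2L * n, -jitter_px, jitter_px), ncol = 2L)
  ))
  out <- vector("list", n)
  k <- 0L
  for (conc in concentrations) {
    for (rep_i in seq_len(replicates)) {
      k <- k + 1L
      spec_k <- base_spec
      spec_k$c_tumor <- conc
      spec_k$seed <- plan$seeds[k]
      if (jitter_px > 0 && spec_k$tumor$type == "ellipse") {
        spec_k$tumor$center_mm <- spec_k$tumor$center_mm +
          plan$jitter[k, ] / spec_k$px_per_mm
      }
      g <- generate_phantom_image(spec_k)
      out[[k]] <- list(image = g$image, truth = g$truth,
                       condition = list(c_tumor = conc,
                                        c_background = base_spec$c_background,
                                        replicate = rep_i))
    }
  }
  out
}
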