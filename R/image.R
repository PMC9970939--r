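# Loading, normalization and cropping of fluorescence images.
#
# All systems are brought onto a common representation: a 2D raster of
# intensities normalized to [0, 1] by the frame maximum, plus a spatial
# calibration in pixels per mm. Because the compared systems differ in bit
# depth and gain, all downstream statistics are relative to the frame maximum.

#' Construct a calibrated fluorescence image
#'
#' @param pixels Numeric matrix of nonnegative intensities. Normalized to
#'   `[0, 1]` via [normalize_to_unit()] unless already normalized.
#' @param px_per_mm Spatial calibration, pixels per mm (> 0).
#' @param source_bit_depth Bit depth of the originating file (8 or 16), or NA.
#' @param provenance Named list of free-text acquisition metadata.
#' @param normalize If `TRUE` (default) normalize the raster by its maximum.
#' @return An object of class `calibrated_image` with fields `pixels`,
#'   `px_per_mm`, `source_bit_depth`, `provenance`, `all_zero`.
#' @export
calibrated_image <- function(pixels, px_per_mm, source_bit_depth = NA_integer_,
                             provenance = list(), normalize = TRUE) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L) {
    stop_nir("invalid_input", "pixels must be a nonempty numeric matrix")
  }
  check_number(px_per_mm, "px_per_mm", min = 0, strict_min = TRUE)
  all_zero <- FALSE
  if (normalize) {
    pixels <- normalize_to_unit(pixels)
    all_zero <- isTRUE(attr(pixels, "all_zero"))
    attr(pixels, "all_zero") <- NULL
  }
  structure(list(pixels = pixels, px_per_mm = px_per_mm,
                 source_bit_depth = as.integer(source_bit_depth),
                 provenance = provenance, all_zero = all_zero),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("calibrated image: %d x %d px (%.1f x %.1f mm), %s-bit source, max %g\n",
              nrow(x$pixels), ncol(x$pixels),
              nrow(x$pixels) / x$px_per_mm, ncol(x$pixels) / x$px_per_mm,
              ifelse(is.na(x$source_bit_depth), "?", x$source_bit_depth),
              max(x$pixels)))
  if (length(x$provenance)) {
    cat("  provenance:", paste(names(x$provenance),
        vapply(x$provenance, function(v) paste(format(v), collapse = " "), ""),
        sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Normalize a raster to unit maximum
#'
#' Divides a nonnegative raster by its maximum so the brightest pixel is 1.
#' This is the common scale on which systems of different bit depth are
#' compared; all reported region statistics are relative to the frame maximum.
#' An all-zero raster is returned unchanged, with attribute `all_zero = TRUE`
#' and a warning.
#'
#' @param pixels Numeric matrix of nonnegative values.
#' @return The normalized matrix. Idempotent and scale-invariant:
#'   `normalize_to_unit(k * x)` equals `normalize_to_unit(x)` for any `k > 0`.
#' @examples
#' normalize_to_unit(matrix(c(0, 5, 10), 1))
#' @export
normalize_to_unit <- function(pixels) {
  if (length(pixels) == 0L) stop_nir("invalid_input", "empty raster")
  if (anyNA(pixels)) stop_nir("invalid_input", "raster contains NA")
  if (any(pixels < 0)) {
    stop_nir("invalid_input",
             "raster contains negative values; subtract background (with clipping) first")
  }
  mx <- max(pixels)
  if (mx == 0) {
    warn_nir("all_zero", "raster is all-zero; returned unchanged")
    attr(pixels, "all_zero") <- TRUE
    return(pixels)
  }
  pixels / mx
}

#' Subtract a dark background frame
#'
#' Pixelwise subtraction of a laser-off dark frame from a fluorescence frame,
#' clipping negative results to zero. Operates on raw (pre-normalization)
#' rasters.
#'
#' @param fluor,dark Numeric matrices of identical dimensions.
#' @return `pmax(fluor - dark, 0)` as a matrix.
#' @export
subtract_background <- function(fluor, dark) {
  if (!is.matrix(fluor) || !is.matrix(dark) || !all(dim(fluor) == dim(dark))) {
    stop_nir("geometry", "fluorescence and dark frames must be matrices of identical shape")
  }
  out <- pmax(fluor - dark, 0)
  dim(out) <- dim(fluor)
  out
}

#' Crop a calibrated image to a box around the phantom
#'
#' The analysis workflow crops each frame to a box around the phantom before
#' segmentation. The crop does NOT re-normalize: normalization is applied on
#' the full frame first (see the vignette for the alternative ordering, which
#' [run_analyze()] exposes via `normalize_after_crop`).
#'
#' @param image A [calibrated_image()].
#' @param box Integer vector `c(row0, col0, height, width)` with 1-based
#'   top-left corner; must lie within the image and have positive area.
#' @return A cropped `calibrated_image` with calibration and provenance kept.
#' @export
crop_to_phantom <- function(image, box) {
  stopifnot(inherits(image, "calibrated_image"))
  box <- as.integer(box)
  if (length(box) != 4L || anyNA(box)) {
    stop_nir("geometry", "box must be c(row0, col0, height, width)")
  }
  r0 <- box[1]; c0 <- box[2]; h <- box[3]; w <- box[4]
  dm <- dim(image$pixels)
  if (h <= 0L || w <= 0L || r0 < 1L || c0 < 1L || r0 + h - 1L > dm[1] || c0 + w - 1L > dm[2]) {
    stop_nir("geometry", "crop box [%d,%d,%d,%d] outside %d x %d image or empty",
             r0, c0, h, w, dm[1], dm[2])
  }
  out <- image
  out$pixels <- image$pixels[r0:(r0 + h - 1L), c0:(c0 + w - 1L), drop = FALSE]
  out$provenance$crop_box <- box
  out
}

rgb_to_gray <- function(arr, weights) {
  weights[1] * arr[, , 1] + weights[2] * arr[, , 2] + weights[3] * arr[, , 3]
}

#' Load a fluorescence image file as a calibrated image
#'
#' Reads a 16-bit grayscale TIFF (research systems) or an 8-bit PNG (clinical
#' systems; RGB is collapsed to one channel with the profile's grayscale
#' weights), then normalizes to unit maximum. Lossy-compressed clinical
#' exports must be converted to PNG beforehand; record the lossy origin via
#' `provenance`.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param profile A [system_profile()] describing the originating system; the
#'   file's channel layout must match it.
#' @param px_per_mm Spatial calibration, pixels per mm. Required: system
#'   intrinsics are not derivable from working distance alone.
#' @param dark Optional dark frame (path or matrix on the same raw scale) to
#'   subtract before normalization.
#' @param provenance Named list of additional acquisition metadata.
#' @return A [calibrated_image()].
#' @export
load_image <- function(path, profile, px_per_mm, dark = NULL, provenance = list()) {
  stopifnot(inherits(profile, "system_profile"))
  if (!file.exists(path)) stop_nir("io", "cannot read '%s': no such file", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    png = png::readPNG(path) * (2^attr_png_depth(path) - 1),
    stop_nir("format", "unsupported image format '.%s' (expected TIFF or PNG)", ext)
  )
  nchan <- if (length(dim(raw)) == 3L) dim(raw)[3] else 1L
  if (profile$channels == "rgb") {
    if (nchan < 3L) {
      stop_nir("format", "profile '%s' expects RGB but '%s' has %d channel(s)",
               profile$name, basename(path), nchan)
    }
    raw <- rgb_to_gray(raw, profile$grayscale_weights)
  } else {
    if (nchan != 1L) {
      stop_nir("format", "profile '%s' expects grayscale but '%s' has %d channels",
               profile$name, basename(path), nchan)
    }
  }
  raw <- as.matrix(raw)
  if (!is.null(dark)) {
    if (is.character(dark)) {
      dark <- load_raw_gray(dark, profile)
    }
    raw <- subtract_background(raw, dark)
  }
  prov <- c(list(system = profile$name, file = basename(path)), provenance)
  calibrated_image(raw, px_per_mm = px_per_mm,
                   source_bit_depth = profile$bit_depth, provenance = prov)
}

# Raw (unnormalized) grayscale read used for dark frames.
load_raw_gray <- function(path, profile) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    png = png::readPNG(path) * (2^attr_png_depth(path) - 1),
    stop_nir("format", "unsupported image format '.%s'", ext)
  )
  if (length(dim(raw)) == 3L) raw <- rgb_to_gray(raw, profile$grayscale_weights)
  as.matrix(raw)
}

# PNG bit depth; png::readPNG always rescales to [0,1], so recover the
# integer scale from the file header (defaults to 8 if unavailable).
attr_png_depth <- function(path) {
  info <- attr(png::readPNG(path, info = TRUE), "info")
  d <- suppressWarnings(as.integer(info$bit.depth %||% 8L))
  if (is.na(d) || d <= 0L) 8L else d
}

#' Write a normalized raster as 32-bit float TIFF
#'
#' @param image A [calibrated_image()] (or a numeric matrix in `[0,1]`).
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "calibrated_image")) image$pixels else image
  tiff::writeTIFF(px, path, bits.per.sample = 32L)
  invisible(path)
}
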