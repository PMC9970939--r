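# Region definition: Otsu-derived intensity bands and fixed-diameter circular
# ROIs at the intensity peak.
#
# Coordinates are (row, col), 1-based, with pixel centers at integer
# coordinates; the row-major index (row - 1) * ncol + col breaks ties
# deterministically.

#' Paired tumor/background region masks
#'
#' Container produced by [otsu_bands()] and [peak_circle_rois()]. The masks
#' are disjoint logical rasters of the image shape, and `params` records
#' everything needed to reconstruct them (see [masks_from_params()]).
#'
#' @param tumor_mask,background_mask Disjoint nonempty logical matrices.
#' @param method `"otsu_bands"` or `"circle_roi"`.
#' @param params Named list of the parameters used.
#' @return An object of class `region_masks`.
#' @export
region_masks <- function(tumor_mask, background_mask, method, params = list()) {
  stopifnot(is.logical(tumor_mask), is.logical(background_mask),
            all(dim(tumor_mask) == dim(background_mask)))
  if (!any(tumor_mask)) stop_nir("empty_region", "tumor mask is empty")
  if (!any(background_mask)) stop_nir("empty_region", "background mask is empty")
  if (any(tumor_mask & background_mask)) {
    stop_nir("invalid_parameter", "tumor and background masks overlap")
  }
  structure(list(tumor_mask = tumor_mask, background_mask = background_mask,
                 method = method, params = params),
            class = "region_masks")
}

#' @export
print.region_masks <- function(x, ...) {
  cat(sprintf("region masks (%s): tumor %d px, background %d px\n",
              x$method, sum(x$tumor_mask), sum(x$background_mask)))
  invisible(x)
}

#' Otsu threshold of a normalized raster
#'
#' Exhaustive maximization of the between-class variance over the interior
#' edges of a `bins`-bin histogram on `[0, 1]`. Class statistics use exact
#' per-bin value sums, so the result coincides with splitting the raw pixel
#' values at each candidate edge. When several edges tie (a plateau between
#' well-separated modes), the midpoint of the tied candidates is returned,
#' following Otsu's original recommendation.
#'
#' @param pixels Numeric matrix with values in `[0, 1]`.
#' @param bins Histogram bin count (default 256).
#' @return The threshold, a value in `(0, 1)`.
#' @export
otsu_threshold <- function(pixels, bins = 256L) {
  x <- as.numeric(pixels)
  if (length(x) < 2L) stop_nir("invalid_input", "need at least 2 pixels")
  if (any(x < 0 | x > 1)) stop_nir("invalid_input", "pixels must be normalized to [0, 1]")
  if (max(x) == min(x)) {
    stop_nir("empty_region", "constant image: Otsu threshold is degenerate (no contrast)")
  }
  bins <- as.integer(bins)
  bin <- pmin(floor(x * bins) + 1L, bins)
  counts <- tabulate(bin, nbins = bins)
  s <- rowsum(x, bin)
  sums_full <- numeric(bins)
  sums_full[as.integer(rownames(s))] <- s[, 1]
  n <- length(x)
  cum_n <- cumsum(counts)[-bins]
  cum_s <- cumsum(sums_full)[-bins]
  w0 <- cum_n / n
  w1 <- 1 - w0
  tot <- sum(x)
  valid <- cum_n > 0L & cum_n < n
  bcv <- numeric(bins - 1L)
  mu0 <- cum_s[valid] / cum_n[valid]
  mu1 <- (tot - cum_s[valid]) / (n - cum_n[valid])
  bcv[valid] <- w0[valid] * w1[valid] * (mu0 - mu1)^2
  edges <- seq_len(bins - 1L) / bins
  mx <- max(bcv)
  tied <- bcv >= mx - 1e-12 * max(mx, 1)
  mean(edges[tied])
}

#' Tumor/background masks from Otsu-derived intensity bands
#'
#' With Otsu threshold `t` of the (cropped, normalized) image, the tumor is
#' all pixels above `tumor_factor * t` ("150% above the threshold" with the
#' default 1.5) and the background is all pixels between `bg_low * t` and
#' `bg_high * t` (10--70% of the threshold by default).
#'
#' @param image A [calibrated_image()].
#' @param tumor_factor Multiple of `t` above which pixels are tumor
#'   (default 1.5).
#' @param bg_low,bg_high Band for background pixels as fractions of `t`
#'   (defaults 0.1 and 0.7). Must satisfy `0 < bg_low < bg_high < tumor_factor`.
#' @param bins Otsu histogram bin count (default 256).
#' @return A [region_masks()] with `params` recording the threshold and bands.
#' @export
otsu_bands <- function(image, tumor_factor = 1.5, bg_low = 0.1, bg_high = 0.7,
                       bins = 256L) {
  stopifnot(inherits(image, "calibrated_image"))
  if (!(0 < bg_low && bg_low < bg_high && bg_high < tumor_factor)) {
    stop_nir("invalid_parameter", "need 0 < bg_low < bg_high < tumor_factor")
  }
  t <- otsu_threshold(image$pixels, bins = bins)
  px <- image$pixels
  tumor <- px > tumor_factor * t
  bg <- px >= bg_low * t & px <= bg_high * t
  if (!any(tumor)) {
    stop_nir("empty_region", "no pixels above %.3g x threshold %.4g (tumor band empty)",
             tumor_factor, t)
  }
  if (!any(bg)) {
    stop_nir("empty_region",
             "no pixels in [%.3g, %.3g] x threshold %.4g (background band empty)",
             bg_low, bg_high, t)
  }
  region_masks(tumor, bg, method = "otsu_bands",
               params = list(threshold = t, tumor_factor = tumor_factor,
                             bg_low = bg_low, bg_high = bg_high, bins = bins))
}

circle_mask <- function(dim, center, radius_px) {
  dr <- outer(seq_len(dim[1]) - center[1], rep(1, dim[2]))
  dc <- outer(rep(1, dim[1]), seq_len(dim[2]) - center[2])
  dr^2 + dc^2 <= radius_px^2
}

# Lowest row-major index among TRUE positions / among maxima.
rowmajor_first <- function(idx, nr, nc) {
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  pick <- which.min((rows - 1L) * nc + cols)
  c(rows[pick], cols[pick])
}

#' Circular ROIs at the intensity peak and in the background
#'
#' The tumor ROI is a circle of diameter `roi_diameter_mm` centered at the
#' global maximum pixel (ties broken to the lowest row-major index). The
#' background ROI is a circle of the same size placed at the deepest interior
#' point of the supplied background region (the argmax of its distance
#' transform); if the circle does not fit entirely inside the background
#' region it is clipped to it, with a warning.
#'
#' @param image A [calibrated_image()] with known `px_per_mm`.
#' @param background_mask Nonempty logical matrix defining the admissible
#'   background region (typically the band from [otsu_bands()], or a
#'   simulation ground-truth mask).
#' @param roi_diameter_mm ROI diameter in mm (default 5).
#' @param background_params Optional list describing how `background_mask`
#'   was derived (stored in `params` so masks can be reconstructed).
#' @return A [region_masks()] whose `params` record both centers, the radius
#'   in pixels, and whether the background circle was clipped.
#' @export
peak_circle_rois <- function(image, background_mask, roi_diameter_mm = 5,
                             background_params = NULL) {
  stopifnot(inherits(image, "calibrated_image"), is.logical(background_mask))
  check_number(roi_diameter_mm, "roi_diameter_mm", min = 0, strict_min = TRUE)
  if (!any(background_mask)) stop_nir("empty_region", "background mask is empty")
  px <- image$pixels
  dm <- dim(px)
  radius_px <- (roi_diameter_mm / 2) * image$px_per_mm
  peak <- rowmajor_first(which(px == max(px)), dm[1], dm[2])
  if (peak[1] - radius_px < 0.5 || peak[1] + radius_px > dm[1] + 0.5 ||
      peak[2] - radius_px < 0.5 || peak[2] + radius_px > dm[2] + 0.5) {
    stop_nir("geometry",
             "%g mm circle at peak (%d, %d) exceeds the %d x %d image",
             roi_diameter_mm, peak[1], peak[2], dm[1], dm[2])
  }
  tumor <- circle_mask(dm, peak, radius_px)
  # Close small noise speckle holes before the distance transform so the
  # "deepest interior point" reflects the region's large-scale shape, not
  # isolated below-band pixels; the circle is still clipped to the true mask.
  # Pad with one FALSE ring so the image border counts as region boundary.
  closed <- as.matrix(EBImage::closing(EBImage::Image(background_mask * 1),
                                       EBImage::makeBrush(7, "disc"))) > 0
  padded <- matrix(FALSE, dm[1] + 2L, dm[2] + 2L)
  padded[2:(dm[1] + 1L), 2:(dm[2] + 1L)] <- closed
  dist <- as.matrix(EBImage::distmap(EBImage::Image(padded * 1)))[2:(dm[1] + 1L),
                                                                  2:(dm[2] + 1L)]
  bg_center <- rowmajor_first(which(dist == max(dist)), dm[1], dm[2])
  bg_circle <- circle_mask(dm, bg_center, radius_px)
  clipped <- any(bg_circle & !background_mask)
  if (clipped) {
    warn_nir("clipped_roi",
             "background circle at (%d, %d) does not fit in the background region; clipped",
             bg_center[1], bg_center[2])
    bg_circle <- bg_circle & background_mask
  }
  bg_circle <- bg_circle & !tumor
  region_masks(tumor, bg_circle, method = "circle_roi",
               params = list(roi_diameter_mm = roi_diameter_mm,
                             radius_px = radius_px,
                             tumor_center = peak, background_center = bg_center,
                             clipped = clipped,
                             background_source = background_params))
}

#' Mean, SD and pixel count within a region
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of the
#' masked pixel intensities. These are the mu and sigma entering the
#' sensitivity metrics.
#'
#' @param image A [calibrated_image()] (or numeric matrix).
#' @param mask Logical matrix with at least 2 `TRUE` pixels.
#' @return An object of class `region_stats`: `mean`, `sd`, `n_pixels`.
#' @export
region_stats <- function(image, mask) {
  px <- if (inherits(image, "calibrated_image")) image$pixels else image
  stopifnot(is.logical(mask), all(dim(mask) == dim(px)))
  vals <- px[mask]
  if (length(vals) < 2L) {
    stop_nir("insufficient_region", "region has %d pixel(s); need >= 2", length(vals))
  }
  structure(list(mean = mean(vals), sd = stats::sd(vals), n_pixels = length(vals)),
            class = "region_stats")
}

#' @export
print.region_stats <- function(x, ...) {
  cat(sprintf("region: mean %.4g, sd %.4g, n = %d\n", x$mean, x$sd, x$n_pixels))
  invisible(x)
}

#' Serialize region-mask parameters to JSON
#'
#' @param masks A [region_masks()].
#' @return A JSON string of `method` and `params`, sufficient (with the
#'   image) to reconstruct the masks via [masks_from_params()].
#' @export
masks_to_json <- function(masks) {
  stopifnot(inherits(masks, "region_masks"))
  jsonlite::toJSON(list(method = masks$method, params = masks$params),
                   auto_unbox = TRUE, digits = NA, null = "null")
}

#' Reconstruct region masks from recorded parameters
#'
#' Rebuilds the exact masks produced earlier from the image and the recorded
#' `method`/`params` (e.g. parsed from [masks_to_json()] output). Otsu-band
#' masks are rebuilt from the stored threshold (Otsu is not re-run); circle
#' masks from the stored centers and radius. A clipped background circle
#' requires a reconstructible background source (Otsu parameters); a
#' background that came from an external mask cannot be rebuilt and raises an
#' error.
#'
#' @param image The [calibrated_image()] the masks were computed on.
#' @param params A list with `method` and `params`, or a JSON string.
#' @return A [region_masks()] identical to the original.
#' @export
masks_from_params <- function(image, params) {
  if (is.character(params)) params <- jsonlite::fromJSON(params)
  p <- params$params
  if (params$method == "otsu_bands") {
    px <- image$pixels
    t <- p$threshold
    return(region_masks(px > p$tumor_factor * t,
                        px >= p$bg_low * t & px <= p$bg_high * t,
                        method = "otsu_bands", params = p))
  }
  if (params$method == "circle_roi") {
    dm <- dim(image$pixels)
    tumor <- circle_mask(dm, as.numeric(p$tumor_center), p$radius_px)
    bg <- circle_mask(dm, as.numeric(p$background_center), p$radius_px)
    if (isTRUE(p$clipped)) {
      src <- p$background_source
      if (is.null(src) || is.null(src$threshold)) {
        stop_nir("invalid_parameter",
                 "clipped background circle with no reconstructible background source")
      }
      allowed <- image$pixels >= src$bg_low * src$threshold &
        image$pixels <= src$bg_high * src$threshold
      bg <- bg & allowed
    }
    bg <- bg & !tumor
    return(region_masks(tumor, bg, method = "circle_roi", params = p))
  }
  stop_nir("invalid_parameter", "unknown mask method '%s'", params$method)
}

#' Write a mask as an 8-bit black/white PNG
#'
#' @param mask Logical matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}
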