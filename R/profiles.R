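#' Sensor noise model
#'
#' A conventional two-stage sensor model: optional Poisson shot noise applied
#' to the pre-quantization intensities (scaled by `shot_noise_gain` photons per
#' intensity unit), followed by additive Gaussian read noise. Neither imaging
#' system's true noise figures are published, so the defaults are placeholders
#' sized to be visible but mild; see the package vignette.
#'
#' @param read_noise_sd Standard deviation of additive Gaussian read noise, in
#'   the simulator's intensity units (the units of the tumor concentration).
#'   `0` disables.
#' @param shot_noise_gain Photons per intensity unit used to scale intensities
#'   before Poisson sampling. `0` disables shot noise.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model()                      # defaults: mild read noise only
#' noise_model(0, 0)                  # noiseless sensor
#' @export
noise_model <- function(read_noise_sd = 0.01, shot_noise_gain = 0) {
  check_number(read_noise_sd, "read_noise_sd", min = 0)
  check_number(shot_noise_gain, "shot_noise_gain", min = 0)
  structure(list(read_noise_sd = read_noise_sd, shot_noise_gain = shot_noise_gain),
            class = "noise_model")
}

#' Imaging-system output profile
#'
#' Describes how an imaging system digitizes the fluorescence field: bit
#' depth, grayscale vs RGB output, whether the system auto-gains (rescales so
#' the frame maximum hits full scale before quantization, emulating clinical
#' display pipelines), and the grayscale conversion weights used when reading
#' RGB output back.
#'
#' @param name Label recorded in image provenance.
#' @param bit_depth 8 or 16.
#' @param channels `"grayscale"` or `"rgb"`.
#' @param auto_gain If `TRUE`, intensities are linearly scaled so the frame
#'   maximum maps to full scale before quantization. If `FALSE`, full scale
#'   corresponds to 1.0 intensity unit and brighter values clip.
#' @param grayscale_weights Three nonnegative coefficients summing to 1 used
#'   to collapse RGB to one channel (default Rec. 709 luma).
#' @return An object of class `system_profile`.
#' @examples
#' system_profile("research")  # 16-bit grayscale, fixed gain
#' system_profile("clinical")  # 8-bit RGB, auto-gain
#' @export
system_profile <- function(name = c("research", "clinical", "custom"),
                           bit_depth = NULL, channels = NULL, auto_gain = NULL,
                           grayscale_weights = c(0.2126, 0.7152, 0.0722)) {
  name <- if (length(name) == 1L) name else match.arg(name)
  defaults <- switch(name,
    research = list(bit_depth = 16L, channels = "grayscale", auto_gain = FALSE),
    clinical = list(bit_depth = 8L, channels = "rgb", auto_gain = TRUE),
    list(bit_depth = 16L, channels = "grayscale", auto_gain = FALSE)
  )
  bit_depth <- as.integer(bit_depth %||% defaults$bit_depth)
  channels <- match.arg(channels %||% defaults$channels, c("grayscale", "rgb"))
  auto_gain <- isTRUE(auto_gain %||% defaults$auto_gain)
  if (!bit_depth %in% c(8L, 16L)) {
    stop_nir("invalid_parameter", "bit_depth must be 8 or 16 (got %d)", bit_depth)
  }
  check_number(grayscale_weights, "grayscale_weights", min = 0, len = 3L)
  if (abs(sum(grayscale_weights) - 1) > 1e-9) {
    stop_nir("invalid_parameter", "grayscale_weights must sum to 1 (sum = %.12g)",
             sum(grayscale_weights))
  }
  structure(list(name = name, bit_depth = bit_depth, channels = channels,
                 auto_gain = auto_gain, grayscale_weights = grayscale_weights),
            class = "system_profile")
}

#' @export
print.system_profile <- function(x, ...) {
  cat(sprintf("system profile '%s': %d-bit %s, auto-gain %s\n",
              x$name, x$bit_depth, x$channels, if (x$auto_gain) "on" else "off"))
  invisible(x)
}
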