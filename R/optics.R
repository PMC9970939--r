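#' Bulk optical properties of a phantom material
#'
#' Absorption and reduced scattering coefficients of the tissue-mimicking bulk
#' material at the fluorophore emission wavelength (~800 nm for ICG-equivalent
#' dyes).
#'
#' @param mu_a Absorption coefficient, mm^-1. Strictly positive.
#' @param mu_s_prime Reduced scattering coefficient, mm^-1. Strictly positive.
#' @return An object of class `optical_properties`.
#' @examples
#' optical_properties(mu_a = 0.005, mu_s_prime = 1.06)  # breast normal tissue
#' @seealso [effective_attenuation()], [optics_presets()]
#' @export
optical_properties <- function(mu_a, mu_s_prime) {
  check_number(mu_a, "mu_a", min = 0, strict_min = TRUE)
  check_number(mu_s_prime, "mu_s_prime", min = 0, strict_min = TRUE)
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("optical properties: mu_a = %g mm^-1, mu_s' = %g mm^-1, mu_eff = %.4f mm^-1\n",
              x$mu_a, x$mu_s_prime, effective_attenuation(x)))
  invisible(x)
}

#' Effective attenuation coefficient (diffusion approximation)
#'
#' Computes `mu_eff = sqrt(3 * mu_a * (mu_a + mu_s_prime))`, the decay constant
#' of diffuse light in bulk tissue. The simulator applies it over the
#' tumor-to-imaging-plane distance to attenuate emission from buried
#' inclusions.
#'
#' @param optics An [optical_properties()] object.
#' @return The effective attenuation coefficient in mm^-1.
#' @examples
#' effective_attenuation(optical_properties(0.005, 1.06))  # ~0.126 mm^-1
#' @export
effective_attenuation <- function(optics) {
  if (!inherits(optics, "optical_properties")) {
    optics <- do.call(optical_properties, as.list(optics)[c("mu_a", "mu_s_prime")])
  }
  sqrt(3 * optics$mu_a * (optics$mu_a + optics$mu_s_prime))
}

#' Optical-property presets for the phantom materials
#'
#' Bulk optical properties of the four phantom materials at 800 nm, as
#' estimated for the 3D-printed tissue-mimicking resins: breast tumor, normal
#' breast, sarcoma, and liver.
#'
#' @param material One of `"breast_tumor"`, `"breast_normal"`, `"sarcoma"`,
#'   `"liver"`.
#' @return An [optical_properties()] object.
#' @examples
#' optics_presets("liver")
#' @export
optics_presets <- function(material = c("breast_normal", "breast_tumor", "sarcoma", "liver")) {
  material <- match.arg(material)
  switch(material,
    breast_tumor  = optical_properties(mu_a = 0.013, mu_s_prime = 0.68),
    breast_normal = optical_properties(mu_a = 0.005, mu_s_prime = 1.06),
    sarcoma       = optical_properties(mu_a = 0.006, mu_s_prime = 0.24),
    liver         = optical_properties(mu_a = 0.143, mu_s_prime = 0.26)
  )
}
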