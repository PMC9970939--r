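test_that("fixed seed gives bit-identical rasters", {
  sp <- phantom_spec(noise = noise_model(0.01, 500), seed = 123L)
  g1 <- generate_phantom_image(sp)
  g2 <- generate_phantom_image(sp)
  expect_identical(g1$image$pixels, g2$image$pixels)
  expect_identical(g1$truth$tumor_mask, g2$truth$tumor_mask)
  g3 <- generate_phantom_image(phantom_spec(noise = noise_model(0.01, 500), seed = 124L))
  expect_false(identical(g1$image$pixels, g3$image$pixels))
})

test_that("pre-quantization tumor/background ratio equals the concentration ratio", {
  g <- generate_phantom_image(clean_spec(c_tumor = 1, c_background = 0.03,
                                         tumor_depth = 0, seed = 1L))
  pq <- g$truth$prequant
  expect_equal(mean(pq[g$truth$tumor_mask]) / mean(pq[g$truth$background_mask]),
               1 / 0.03, tolerance = 1e-12)
  # quantized 16-bit image preserves it to quantization precision
  px <- g$image$pixels
  expect_equal(mean(px[g$truth$tumor_mask]) / mean(px[g$truth$background_mask]),
               33.33, tolerance = 1e-2)
})

test_that("depth attenuates tumor emission by exp(-mu_eff * depth)", {
  at_depth <- function(d) {
    g <- generate_phantom_image(clean_spec(tumor_depth = d, seed = 1L))
    max(g$truth$prequant)
  }
  # breast-normal optics, 2.2 mm: exp(-0.1264 * 2.2) = 0.757
  expect_equal(at_depth(2.2) / at_depth(0), 0.757, tolerance = 1e-3)
})

test_that("equal concentrations give a uniform phantom footprint", {
  g <- generate_phantom_image(clean_spec(c_tumor = 0.3, c_background = 0.3,
                                         tumor_depth = 0, seed = 1L))
  expect_equal(max(g$truth$prequant) - min(g$truth$prequant), 0)
})

test_that("illumination field is zero-mean multiplicative with bounded amplitude", {
  for (amp in c(0.02, 0.05, 0.3)) {
    f <- nirphantom:::with_seed(9L, nirphantom:::illumination_field(c(64L, 80L), amp))
    expect_equal(mean(f), 1, tolerance = 1e-6)
    expect_lte(max(abs(f - 1)), amp + 1e-12)
    expect_true(all(f > 0))
  }
})

test_that("Gaussian blur with a unit-sum kernel never raises the maximum", {
  g0 <- generate_phantom_image(clean_spec(seed = 2L))
  prev <- Inf
  for (sig in c(0, 0.5, 1, 2, 4)) {
    g <- generate_phantom_image(clean_spec(blur_sigma = sig, seed = 2L))
    expect_lte(max(g$truth$prequant), max(g0$truth$prequant) + 1e-12)
    expect_lte(max(g$truth$prequant), prev + 1e-12)
    prev <- max(g$truth$prequant)
  }
})

test_that("8-bit quantization never exceeds 256 distinct levels", {
  sp <- phantom_spec(system = system_profile("clinical"),
                     noise = noise_model(0.02, 0), seed = 5L)
  g <- generate_phantom_image(sp)
  expect_lte(length(unique(as.numeric(g$image$pixels))), 256L)
  # auto-gain maps the frame maximum to full scale
  expect_equal(max(g$image$pixels), 1)
})

test_that("tumor geometry escaping the frame is a geometry error", {
  expect_error(
    generate_phantom_image(phantom_spec(
      tumor = tumor_ellipse(c(3, 25.6), c(14.25, 10.5)))),
    class = "nirphantom_geometry")
  expect_error(
    generate_phantom_image(phantom_spec(
      tumor = tumor_raster(matrix(TRUE, 10, 10)))),
    class = "nirphantom_geometry")
})

test_that("ground-truth masks are disjoint and exclude a dilation ring", {
  g <- generate_phantom_image(phantom_spec(seed = 3L))
  expect_false(any(g$truth$tumor_mask & g$truth$background_mask))
  # ring: pixels adjacent to the tumor are in neither mask
  expect_lt(sum(g$truth$tumor_mask) + sum(g$truth$background_mask),
            length(g$truth$tumor_mask))
  expect_false(g$truth$ratio_defined && FALSE)
  g0 <- generate_phantom_image(phantom_spec(c_background = 0, seed = 3L))
  expect_false(g0$truth$ratio_defined)
  expect_true(is.na(g0$truth$true_ratio))
})

test_that("concentration series has the right size, determinism and jitter behavior", {
  base <- phantom_spec(image_shape = c(128L, 128L),
                       tumor = tumor_ellipse(c(12.8, 12.8), c(6, 4)),
                       noise = noise_model(0.01, 0), seed = 21L)
  s1 <- generate_concentration_series(base, c(0.03, 0.1, 0.3, 1), replicates = 3L)
  expect_length(s1, 12L)
  expect_equal(sum(vapply(s1, function(x) x$condition$c_tumor, 0) == 1), 3L)
  s2 <- generate_concentration_series(base, c(0.03, 0.1, 0.3, 1), replicates = 3L)
  expect_identical(lapply(s1, function(x) x$image$pixels),
                   lapply(s2, function(x) x$image$pixels))
  # replicate images differ (noise + jitter) under the default settings
  expect_false(identical(s1[[1]]$image$pixels, s1[[2]]$image$pixels))
  # with noise, jitter and illumination randomness off, replicates coincide
  quiet <- clean_spec(image_shape = c(128L, 128L),
                      tumor = tumor_ellipse(c(12.8, 12.8), c(6, 4)), seed = 21L)
  s3 <- generate_concentration_series(quiet, c(0.1, 1), replicates = 2L, jitter_px = 0)
  expect_identical(s3[[1]]$image$pixels, s3[[2]]$image$pixels)
  expect_error(generate_concentration_series(base, c(-0.1, 1)),
               class = "nirphantom_invalid_parameter")
  expect_error(generate_concentration_series(base, numeric(0)),
               class = "nirphantom_invalid_parameter")
})
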