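test_that("Otsu threshold equals brute-force between-class-variance maximization", {
  set.seed(11)
  for (i in 1:50) {
    x <- matrix(runif(64), 8)
    expect_equal(otsu_threshold(x), oracle_otsu(x), tolerance = 1e-12)
  }
})

test_that("Otsu threshold agrees with EBImage on continuous images", {
  set.seed(12)
  x <- matrix(runif(4096), 64)
  # conventions differ by at most one bin edge
  expect_lt(abs(otsu_threshold(x) - EBImage::otsu(x, range = c(0, 1))), 1.5 / 256)
})

test_that("bimodal image splits into the expected bands", {
  px <- matrix(rep(c(0.1, 0.9), each = 32), 8)
  t <- otsu_threshold(px)
  expect_gt(t, 0.1 / 0.7)   # background band must reach the 0.1 pixels
  expect_lt(t, 0.9 / 1.5)   # tumor band must reach the 0.9 pixels
  img <- calibrated_image(px, px_per_mm = 1, normalize = FALSE)
  m <- otsu_bands(img)
  expect_identical(m$tumor_mask, px == 0.9)
  expect_identical(m$background_mask, px == 0.1)
  expect_equal(m$params$threshold, t)
})

test_that("degenerate images raise empty-region errors naming the failure", {
  img <- calibrated_image(matrix(0.5, 8, 8), px_per_mm = 1, normalize = FALSE)
  expect_error(otsu_bands(img), class = "nirphantom_empty_region")
  # all pixels strictly between the bands: tumor band empty
  px <- matrix(rep(c(0.45, 0.55), each = 32), 8)
  img2 <- calibrated_image(px, px_per_mm = 1, normalize = FALSE)
  expect_error(otsu_bands(img2), class = "nirphantom_empty_region")
  expect_error(otsu_bands(img2), "tumor band")
})

test_that("band masks are unchanged by positive rescaling of the raw image", {
  set.seed(13)
  raw <- matrix(runif(4096)^2, 64)
  m1 <- otsu_bands(calibrated_image(raw, 1))
  m2 <- otsu_bands(calibrated_image(7.3 * raw, 1))
  expect_identical(m1$tumor_mask, m2$tumor_mask)
  expect_identical(m1$background_mask, m2$background_mask)
})

test_that("band factor ordering is validated", {
  img <- calibrated_image(matrix(runif(64), 8), 1)
  expect_error(otsu_bands(img, bg_low = 0.8, bg_high = 0.7),
               class = "nirphantom_invalid_parameter")
  expect_error(otsu_bands(img, tumor_factor = 0.5),
               class = "nirphantom_invalid_parameter")
})

test_that("peak circle has the documented geometry and pixel count", {
  px <- matrix(0.1, 100, 100)
  px[50, 50] <- 1
  img <- calibrated_image(px, px_per_mm = 10, normalize = FALSE)
  bg <- matrix(TRUE, 100, 100)
  bg[30:70, 30:70] <- FALSE
  m <- suppressWarnings(peak_circle_rois(img, bg, roi_diameter_mm = 5))
  expect_equal(m$params$tumor_center, c(50, 50))
  expect_equal(m$params$radius_px, 25)
  n <- sum(m$tumor_mask)
  expect_gte(n, 1941); expect_lte(n, 1985)   # pi * 25^2 +/- boundary pixels
  expect_true(m$tumor_mask[50, 50])          # circle always contains the peak
  # exhaustive pixel-center-in-circle recount
  expect_equal(n, sum(outer((1:100 - 50)^2, (1:100 - 50)^2, "+") <= 625))
})

test_that("peak ties break to the lowest row-major index", {
  px <- matrix(0, 60, 100)
  px[10, 20] <- 1
  px[5, 40] <- 1   # row-major index 440 < 920: wins
  img <- calibrated_image(px, px_per_mm = 1, normalize = FALSE)
  m <- suppressWarnings(peak_circle_rois(img, px == 0, roi_diameter_mm = 4))
  expect_equal(m$params$tumor_center, c(5, 40))
})

test_that("circle exceeding image bounds and tight background regions are handled", {
  px <- matrix(0.1, 50, 50); px[2, 2] <- 1
  img <- calibrated_image(px, px_per_mm = 10, normalize = FALSE)
  expect_error(peak_circle_rois(img, px < 0.5, roi_diameter_mm = 5),
               class = "nirphantom_geometry")
  # background region smaller than the circle: clipped with a warning
  px2 <- matrix(0.1, 60, 60); px2[30, 30] <- 1
  img2 <- calibrated_image(px2, px_per_mm = 10, normalize = FALSE)
  bg <- matrix(FALSE, 60, 60); bg[45:55, 45:55] <- TRUE
  expect_warning(m <- peak_circle_rois(img2, bg, roi_diameter_mm = 5),
                 class = "nirphantom_clipped_roi")
  expect_true(all(bg[m$background_mask]))
  expect_true(m$params$clipped)
})

test_that("region statistics use the sample standard deviation", {
  px <- matrix(c(0.2, 0.4, 0.6, 0.8), 2)
  s <- region_stats(px, matrix(TRUE, 2, 2))
  expect_equal(s$mean, 0.5)
  expect_equal(s$sd, sqrt(mean((c(0.2, 0.4, 0.6, 0.8) - 0.5)^2) * 4 / 3))
  expect_equal(s$sd, 0.2582, tolerance = 1e-4)
  expect_equal(s$n_pixels, 4L)
  s2 <- region_stats(matrix(0.3, 1, 3), matrix(TRUE, 1, 3))
  expect_equal(s2$sd, 0)
  expect_error(region_stats(px, matrix(FALSE, 2, 2)),
               class = "nirphantom_insufficient_region")
  mask1 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2)
  expect_error(region_stats(px, mask1), class = "nirphantom_insufficient_region")
})

test_that("mask parameters reconstruct the masks exactly through JSON", {
  g <- generate_phantom_image(peaked_spec(31))
  ot <- otsu_bands(g$image)
  ot2 <- masks_from_params(g$image, masks_to_json(ot))
  expect_identical(ot$tumor_mask, ot2$tumor_mask)
  expect_identical(ot$background_mask, ot2$background_mask)
  ci <- suppressWarnings(peak_circle_rois(g$image, ot$background_mask, 5,
                                          background_params = c(list(type = "otsu"),
                                                                ot$params)))
  ci2 <- masks_from_params(g$image, masks_to_json(ci))
  expect_identical(ci$tumor_mask, ci2$tumor_mask)
  expect_identical(ci$background_mask, ci2$background_mask)
})

test_that("tumor and background masks are always disjoint", {
  for (s in 1:5) {
    g <- generate_phantom_image(peaked_spec(s))
    ot <- otsu_bands(g$image)
    expect_false(any(ot$tumor_mask & ot$background_mask))
    ci <- suppressWarnings(peak_circle_rois(g$image, ot$background_mask, 5))
    expect_false(any(ci$tumor_mask & ci$background_mask))
  }
})
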