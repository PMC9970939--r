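mk_set <- function(sbr, method = "otsu_bands", roi = NA_real_) {
  structure(list(sbr = sbr, snr = sbr + 1, cnr = sbr - 1, cvr = sbr / 2,
                 method = method, roi_diameter_mm = roi, undefined = list()),
            class = "metric_set")
}

test_that("replicate aggregation gives mean and SD/sqrt(n) standard error", {
  agg <- aggregate_replicates(lapply(c(4, 5, 6), mk_set))
  expect_equal(agg$sbr$mean, 5)
  expect_equal(agg$sbr$se, 1 / sqrt(3))
  expect_equal(agg$sbr$se, 0.5774, tolerance = 1e-4)
  expect_equal(agg$n_replicates, 3L)
  # identical replicates: zero SE
  expect_equal(aggregate_replicates(lapply(c(2, 2, 2), mk_set))$sbr$se, 0)
  # single replicate: mean = value, SE missing
  one <- aggregate_replicates(list(mk_set(7)))
  expect_equal(one$sbr$mean, 7)
  expect_true(is.na(one$sbr$se))
  # the mean always lies within the replicate range
  set.seed(3)
  for (i in 1:10) {
    v <- runif(5, 0, 30)
    a <- aggregate_replicates(lapply(v, mk_set))
    expect_gte(a$sbr$mean, min(v)); expect_lte(a$sbr$mean, max(v))
  }
})

test_that("mixing conditions in one aggregation is a grouping error", {
  expect_error(aggregate_replicates(list(mk_set(4), mk_set(5, method = "circle_roi"))),
               class = "nirphantom_grouping")
  expect_error(aggregate_replicates(list()), class = "nirphantom_invalid_parameter")
})

test_that("undefined replicate values are dropped with their count reported", {
  sets <- lapply(c(4, 6), mk_set)
  sets[[3]] <- mk_set(NA_real_)
  agg <- aggregate_replicates(sets)
  expect_equal(agg$sbr$mean, 5)
  expect_equal(agg$sbr$n, 2L)
})

small_series <- function(seed = 5L, c_background = 0.03,
                         concentrations = c(0.1, 0.3, 1), replicates = 2L) {
  base <- phantom_spec(tumor = tumor_ellipse(c(25.6, 25.6), c(8, 6)),
                       c_background = c_background, blur_sigma = 3,
                       noise = noise_model(0.01, 0), seed = seed)
  generate_concentration_series(base, concentrations, replicates)
}

test_that("concentration sweep produces the full condition grid", {
  sw <- concentration_sweep(small_series(), background = "truth")
  expect_s3_class(sw, "concentration_sweep")
  expect_equal(nrow(sw), 3L * 2L)  # 3 concentrations x 2 methods
  expect_setequal(unique(sw$method), c("otsu_bands", "circle_roi"))
  expect_true(all(sw$n == 2L))
  expect_true(all(is.finite(sw$sbr_mean)))
  expect_true(all(sw$sbr_se >= 0))
})

test_that("mean SBR is non-decreasing in tumor concentration for each method", {
  sw <- concentration_sweep(small_series(seed = 6L), background = "truth")
  for (m in unique(sw$method)) {
    v <- sw$sbr_mean[sw$method == m][order(sw$c_tumor[sw$method == m])]
    expect_true(all(diff(v) >= 0))
  }
})

test_that("raising the background concentration lowers the mean CNR", {
  cnr_at <- function(cb) {
    sw <- concentration_sweep(small_series(seed = 9L, c_background = cb,
                                           concentrations = 1, replicates = 3L),
                              methods = "circle_roi", background = "truth")
    sw$cnr_mean
  }
  expect_gt(cnr_at(0), cnr_at(0.03))
})

test_that("segmentation failures become recorded failed cells, not crashes", {
  # zero-contrast noiseless images: Otsu degenerates at every replicate
  base <- phantom_spec(c_tumor = 0.03, c_background = 0.03, tumor_depth = 0,
                       blur_sigma = 0, field_inhomogeneity_amplitude = 0,
                       noise = noise_model(0, 0), seed = 2L)
  series <- generate_concentration_series(base, 0.03, replicates = 2L, jitter_px = 0)
  sw <- concentration_sweep(series, methods = "otsu_bands")
  expect_equal(nrow(sw), 1L)
  expect_true(sw$failed)
  expect_match(sw$note, "otsu")
  expect_true(is.na(sw$sbr_mean))
})

test_that("the metric grid is shaped system x background with paired method columns", {
  entries <- list()
  for (sys in c("research", "clinical")) {
    for (cb in c(0, 0.03)) {
      g <- generate_phantom_image(
        phantom_spec(tumor = tumor_ellipse(c(25.6, 25.6), c(8, 6)),
                     c_background = cb, blur_sigma = 3,
                     system = system_profile(sys),
                     noise = noise_model(0.01, 0), seed = 13L))
      entries[[length(entries) + 1L]] <-
        list(image = g$image, truth = g$truth, phantom = "breast",
             background = if (cb > 0) "3% ICG BG" else "No BG", system = sys)
    }
  }
  grid <- metric_grid(entries, background = "truth")
  expect_equal(nrow(grid), 4L)
  metric_cols <- as.vector(outer(c("sbr", "snr", "cnr", "cvr"),
                                 c("otsu", "circle"), paste, sep = "_"))
  expect_true(all(metric_cols %in% names(grid)))
  # circle ROI skews SBR above the Otsu bands in every row
  expect_true(all(grid$sbr_circle >= grid$sbr_otsu, na.rm = TRUE))
  # rendering at 2 significant figures happens only at format time
  fmt <- format_metric_grid(grid)
  expect_true(is.character(fmt$sbr_otsu))
  expect_equal(fmt$sbr_otsu[1], trimws(format(signif(grid$sbr_otsu[1], 2))))
  expect_error(metric_grid(entries[c(1, 1)]), class = "nirphantom_labeling")
  expect_error(metric_grid(list()), class = "nirphantom_invalid_parameter")
})

test_that("sweep tables are a pure function of their inputs", {
  s <- small_series(seed = 8L, concentrations = c(0.3, 1), replicates = 2L)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(concentration_sweep(s, background = "truth"), f1, row.names = FALSE)
  write.csv(concentration_sweep(s, background = "truth"), f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
})
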