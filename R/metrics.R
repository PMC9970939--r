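# The four sensitivity metrics. All are dimensionless ratios of region
# statistics and therefore invariant to positive rescaling of the image;
# CNR and CVR are additionally invariant to a constant offset.
#
#   SBR = mu_T / mu_B
#   SNR = mu_T / sigma_B
#   CNR = (mu_T - mu_B) / sigma_B
#   CVR = (mu_T - mu_B) / sqrt(sigma_T^2 + sigma_B^2)
#
# Zero denominators raise typed "undefined metric" errors; reports serialize
# such cells as null, never as sentinel numbers, so "undefined" is always
# distinguishable from "large".

as_region_stats <- function(x, name) {
  if (inherits(x, "region_stats")) return(x)
  if (is.list(x) && all(c("mean", "sd") %in% names(x))) {
    return(structure(list(mean = x$mean, sd = x$sd,
                          n_pixels = x$n_pixels %||% NA_integer_),
                     class = "region_stats"))
  }
  stop_nir("invalid_parameter", "`%s` must be region_stats (or list with mean, sd)", name)
}

#' Signal-to-background ratio
#'
#' `SBR = mu_T / mu_B`: mean tumor intensity over mean background intensity.
#'
#' @param tumor,background [region_stats()] of the tumor and background
#'   regions (lists with `mean` and `sd` are accepted).
#' @return The ratio, a nonnegative number.
#' @examples
#' sbr(list(mean = 0.5, sd = 0.1), list(mean = 0.1, sd = 0.02))  # 5
#' @export
sbr <- function(tumor, background) {
  tumor <- as_region_stats(tumor, "tumor")
  background <- as_region_stats(background, "background")
  if (background$mean <= 0) {
    stop_nir("undefined_metric", "SBR undefined: background mean is %g", background$mean)
  }
  tumor$mean / background$mean
}

#' Signal-to-noise ratio
#'
#' `SNR = mu_T / sigma_B`: mean tumor intensity over the background standard
#' deviation.
#'
#' @inheritParams sbr
#' @return The ratio.
#' @export
snr <- function(tumor, background) {
  tumor <- as_region_stats(tumor, "tumor")
  background <- as_region_stats(background, "background")
  if (background$sd <= 0) {
    stop_nir("undefined_metric", "SNR undefined: background SD is %g", background$sd)
  }
  tumor$mean / background$sd
}

#' Contrast-to-noise ratio
#'
#' `CNR = (mu_T - mu_B) / sigma_B`. May be negative when the tumor region is
#' dimmer than the background. Identity: `CNR = SNR - mu_B / sigma_B`.
#'
#' @inheritParams sbr
#' @return The ratio.
#' @export
cnr <- function(tumor, background) {
  tumor <- as_region_stats(tumor, "tumor")
  background <- as_region_stats(background, "background")
  if (background$sd <= 0) {
    stop_nir("undefined_metric", "CNR undefined: background SD is %g", background$sd)
  }
  (tumor$mean - background$mean) / background$sd
}

#' Contrast-to-variability ratio
#'
#' `CVR = (mu_T - mu_B) / sqrt(sigma_T^2 + sigma_B^2)`: the contrast
#' normalized by the pooled variability of both regions, a discriminability
#' measure closely related to an ideal-observer detectability index. Since
#' its denominator dominates the CNR denominator, `CVR <= CNR` whenever
#' `mu_T >= mu_B`.
#'
#' @inheritParams sbr
#' @return The ratio.
#' @export
cvr <- function(tumor, background) {
  tumor <- as_region_stats(tumor, "tumor")
  background <- as_region_stats(background, "background")
  denom2 <- tumor$sd^2 + background$sd^2
  if (denom2 <= 0) {
    stop_nir("undefined_metric", "CVR undefined: both region SDs are zero")
  }
  (tumor$mean - background$mean) / sqrt(denom2)
}

#' Compute all four sensitivity metrics for one image and mask pair
#'
#' Runs [region_stats()] on both masks, then SBR, SNR, CNR and CVR. Metrics
#' whose denominator is zero are recorded as `NA` with the reason kept in
#' `undefined`, so a degenerate region never aborts a batch.
#'
#' @param image A [calibrated_image()].
#' @param masks A [region_masks()].
#' @param source Image identifier carried into the result.
#' @return An object of class `metric_set`: `sbr`, `snr`, `cnr`, `cvr`
#'   (numbers or `NA`), `undefined` (named reasons for `NA` cells), `method`,
#'   `roi_diameter_mm`, `source`, `tumor`, `background` (the region stats),
#'   `params`.
#' @export
compute_metrics <- function(image, masks, source = NA_character_) {
  stopifnot(inherits(masks, "region_masks"))
  tum <- region_stats(image, masks$tumor_mask)
  bg <- region_stats(image, masks$background_mask)
  undefined <- list()
  value_or_na <- function(name, fn) {
    tryCatch(fn(tum, bg), nirphantom_undefined_metric = function(e) {
      undefined[[name]] <<- conditionMessage(e)
      NA_real_
    })
  }
  structure(list(
    sbr = value_or_na("sbr", sbr),
    snr = value_or_na("snr", snr),
    cnr = value_or_na("cnr", cnr),
    cvr = value_or_na("cvr", cvr),
    undefined = undefined,
    method = masks$method,
    roi_diameter_mm = masks$params$roi_diameter_mm %||% NA_real_,
    source = source,
    tumor = tum, background = bg,
    params = masks$params
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else format(signif(v, 4))
  cat(sprintf("metrics (%s%s): SBR %s, SNR %s, CNR %s, CVR %s\n",
              x$method,
              if (!is.na(x$roi_diameter_mm)) sprintf(", %g mm", x$roi_diameter_mm) else "",
              fmt(x$sbr), fmt(x$snr), fmt(x$cnr), fmt(x$cvr)))
  invisible(x)
}

#' @export
as.data.frame.metric_set <- function(x, ...) {
  data.frame(image = x$source, method = x$method,
             roi_mm = x$roi_diameter_mm,
             sbr = x$sbr, snr = x$snr, cnr = x$cnr, cvr = x$cvr,
             stringsAsFactors = FALSE)
}

#' Serialize a metric set to JSON
#'
#' Undefined metrics serialize as `null`.
#'
#' @param x A `metric_set`.
#' @return A JSON string.
#' @export
metrics_to_json <- function(x) {
  stopifnot(inherits(x, "metric_set"))
  jsonlite::toJSON(list(image = x$source, method = x$method,
                        roi_mm = x$roi_diameter_mm,
                        sbr = x$sbr, snr = x$snr, cnr = x$cnr, cvr = x$cvr,
                        undefined = x$undefined),
                   auto_unbox = TRUE, digits = NA, na = "null", null = "null")
}
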