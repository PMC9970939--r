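# Study-level aggregation: replicate summaries, concentration sweeps, and the
# system x background x method metric grid.

metric_names <- c("sbr", "snr", "cnr", "cvr")

#' Aggregate metric sets over replicates
#'
#' Per-metric mean and standard error over replicate acquisitions of the same
#' condition. The standard error is the sample SD of the replicate-level
#' metric values divided by `sqrt(n)` (not pixel-level pooling); it is
#' reported as `NA` for a single replicate. Undefined (NA) metric values are
#' dropped per metric, with the count of contributing replicates kept.
#'
#' @param metric_sets Nonempty list of `metric_set` objects from one
#'   condition (same method and ROI size).
#' @return An object of class `replicate_summary`: per metric `mean`, `se`
#'   and `n`; plus `method`, `roi_diameter_mm`, `n_replicates`.
#' @examples
#' ms <- lapply(c(4, 5, 6), function(v)
#'   structure(list(sbr = v, snr = NA, cnr = NA, cvr = NA,
#'                  method = "otsu_bands", roi_diameter_mm = NA),
#'             class = "metric_set"))
#' aggregate_replicates(ms)$sbr  # mean 5, se 0.577
#' @export
aggregate_replicates <- function(metric_sets) {
  if (length(metric_sets) == 0L) stop_nir("invalid_parameter", "empty replicate list")
  stopifnot(all(vapply(metric_sets, inherits, TRUE, "metric_set")))
  methods <- unique(vapply(metric_sets, `[[`, "", "method"))
  rois <- unique(vapply(metric_sets, function(m) m$roi_diameter_mm %||% NA_real_, 0))
  if (length(methods) != 1L || length(rois) != 1L) {
    stop_nir("grouping", "replicates mix methods (%s) or ROI sizes",
             paste(methods, collapse = ", "))
  }
  out <- list(method = methods, roi_diameter_mm = rois,
              n_replicates = length(metric_sets))
  for (m in metric_names) {
    vals <- vapply(metric_sets, function(s) s[[m]] %||% NA_real_, 0)
    vals <- vals[!is.na(vals)]
    n <- length(vals)
    out[[m]] <- list(
      mean = if (n > 0) mean(vals) else NA_real_,
      se = if (n > 1) stats::sd(vals) / sqrt(n) else NA_real_,
      n = n
    )
  }
  structure(out, class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("replicate summary (%s, n = %d):\n", x$method, x$n_replicates))
  for (m in metric_names) {
    cat(sprintf("  %s: %.4g +/- %.3g (n = %d)\n", toupper(m),
                x[[m]]$mean, x[[m]]$se, x[[m]]$n))
  }
  invisible(x)
}

# Compute metric sets for one image under the requested methods / ROI sizes.
# `background` picks where the circle-ROI background region comes from:
# the Otsu band (as in the physical-image analysis) or the simulation
# ground-truth background mask. Failures are captured, not raised.
analyze_one <- function(image, truth = NULL, methods = c("otsu_bands", "circle_roi"),
                        roi_diameters_mm = 5,
                        background = c("otsu", "truth"),
                        tumor_factor = 1.5, bg_low = 0.1, bg_high = 0.7,
                        bins = 256L, source = NA_character_) {
  background <- match.arg(background)
  results <- list()
  failures <- list()
  otsu_masks <- tryCatch(
    otsu_bands(image, tumor_factor, bg_low, bg_high, bins),
    nirphantom_error = function(e) e
  )
  if ("otsu_bands" %in% methods) {
    if (inherits(otsu_masks, "error")) {
      failures[["otsu_bands"]] <- conditionMessage(otsu_masks)
    } else {
      results[["otsu_bands"]] <- compute_metrics(image, otsu_masks, source = source)
    }
  }
  if ("circle_roi" %in% methods) {
    bg_mask <- NULL
    bg_params <- NULL
    if (background == "truth" && !is.null(truth)) {
      bg_mask <- truth$background_mask
      bg_params <- list(type = "truth")
    } else if (!inherits(otsu_masks, "error")) {
      bg_mask <- otsu_masks$background_mask
      bg_params <- c(list(type = "otsu"), otsu_masks$params)
    }
    for (d in roi_diameters_mm) {
      key <- sprintf("circle_roi_%g", d)
      if (is.null(bg_mask)) {
        failures[[key]] <- "no background region available for circle ROI"
        next
      }
      res <- tryCatch(
        suppressWarnings(compute_metrics(
          image, peak_circle_rois(image, bg_mask, d, background_params = bg_params),
          source = source)),
        nirphantom_error = function(e) e
      )
      if (inherits(res, "error")) failures[[key]] <- conditionMessage(res)
      else results[[key]] <- res
    }
  }
  list(results = results, failures = failures)
}

#' Sweep metrics over a replicated concentration series
#'
#' Computes all requested metric sets for every image of a series (e.g. from
#' [generate_concentration_series()]) and aggregates replicates per
#' condition, yielding the machine-readable counterpart of a
#' metric-vs-concentration figure: one row per (tumor concentration,
#' background concentration, method, ROI size) with per-metric means and
#' standard errors over replicates. Per-cell segmentation failures (typical
#' at the lowest contrast) are recorded in the `failed`/`note` columns, never
#' dropped silently.
#'
#' @param series List of `list(image, truth, condition)` entries; `condition`
#'   must contain `c_tumor`, `c_background`, `replicate`.
#' @param methods Segmentation methods to run (default both).
#' @param roi_diameters_mm Circle-ROI diameters in mm (default 5).
#' @param background Background-region source for the circle ROI: `"otsu"`
#'   (the Otsu band, as for physical images) or `"truth"` (simulation
#'   ground-truth background mask).
#' @param ... Segmentation parameters passed to [otsu_bands()]
#'   (`tumor_factor`, `bg_low`, `bg_high`, `bins`).
#' @return A `data.frame` of class `concentration_sweep` with columns
#'   `c_tumor`, `c_background`, `method`, `roi_mm`, `n`, per-metric
#'   `<m>_mean` / `<m>_se`, `failed`, `note`.
#' @export
concentration_sweep <- function(series, methods = c("otsu_bands", "circle_roi"),
                                roi_diameters_mm = 5,
                                background = c("otsu", "truth"), ...) {
  if (length(series) == 0L) stop_nir("invalid_parameter", "empty series")
  if (length(methods) == 0L) stop_nir("invalid_parameter", "empty method list")
  background <- match.arg(background)
  conds <- vapply(series, function(s)
    paste(s$condition$c_tumor, s$condition$c_background, sep = "|"), "")
  rows <- list()
  for (cond in unique(conds)) {
    idx <- which(conds == cond)
    per_key <- list()   # key -> list of metric_set
    notes <- character()
    for (i in idx) {
      s <- series[[i]]
      a <- analyze_one(s$image, s$truth, methods = methods,
                       roi_diameters_mm = roi_diameters_mm,
                       background = background,
                       source = sprintf("c%g_r%d", s$condition$c_tumor,
                                        s$condition$replicate), ...)
      for (key in names(a$results)) per_key[[key]] <- c(per_key[[key]], list(a$results[[key]]))
      for (key in names(a$failures)) {
        notes <- c(notes, sprintf("%s rep %d: %s", key, s$condition$replicate,
                                  a$failures[[key]]))
      }
    }
    c_t <- series[[idx[1]]]$condition$c_tumor
    c_b <- series[[idx[1]]]$condition$c_background
    keys <- c(if ("otsu_bands" %in% methods) "otsu_bands",
              if ("circle_roi" %in% methods) sprintf("circle_roi_%g", roi_diameters_mm))
    for (key in keys) {
      sets <- per_key[[key]]
      method <- if (key == "otsu_bands") "otsu_bands" else "circle_roi"
      roi <- if (method == "circle_roi")
        as.numeric(sub("circle_roi_", "", key)) else NA_real_
      row <- list(c_tumor = c_t, c_background = c_b, method = method,
                  roi_mm = roi, n = length(sets) %||% 0L)
      if (length(sets) > 0) {
        agg <- aggregate_replicates(sets)
        for (m in metric_names) {
          row[[paste0(m, "_mean")]] <- agg[[m]]$mean
          row[[paste0(m, "_se")]] <- agg[[m]]$se
        }
        row$failed <- length(sets) < length(idx)
      } else {
        for (m in metric_names) {
          row[[paste0(m, "_mean")]] <- NA_real_
          row[[paste0(m, "_se")]] <- NA_real_
        }
        row$failed <- TRUE
      }
      key_notes <- notes[startsWith(notes, key)]
      row$note <- if (length(key_notes)) paste(key_notes, collapse = "; ") else ""
      rows[[length(rows) + 1L]] <- row
    }
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  df <- df[order(df$c_background, df$method, df$roi_mm, df$c_tumor,
                 na.last = TRUE), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("concentration_sweep", "data.frame")
  df
}

#' Plot a concentration sweep (metric vs tumor concentration)
#'
#' Log-x plot of one metric against tumor concentration, one line per
#' (method, ROI, background concentration), with standard-error bars over
#' replicates.
#'
#' @param x A `concentration_sweep`.
#' @param metric One of `"sbr"`, `"snr"`, `"cnr"`, `"cvr"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.concentration_sweep <- function(x, metric = "sbr", ...) {
  metric <- match.arg(metric, metric_names)
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_se")
  ok <- !is.na(x[[mcol]])
  if (!any(ok)) stop_nir("invalid_input", "no defined values of %s to plot", metric)
  grp <- interaction(x$method, x$roi_mm, x$c_background, drop = TRUE)
  cols <- grDevices::hcl.colors(nlevels(grp), "Dark 3")
  ylim <- range(c(x[[mcol]][ok] - ifelse(is.na(x[[scol]][ok]), 0, x[[scol]][ok]),
                  x[[mcol]][ok] + ifelse(is.na(x[[scol]][ok]), 0, x[[scol]][ok])))
  graphics::plot(NA, xlim = range(x$c_tumor), ylim = ylim, log = "x",
                 xlab = "tumor concentration (uM)", ylab = toupper(metric), ...)
  for (g in seq_len(nlevels(grp))) {
    sub <- x[grp == levels(grp)[g] & ok, , drop = FALSE]
    sub <- sub[order(sub$c_tumor), , drop = FALSE]
    if (nrow(sub) == 0) next
    graphics::lines(sub$c_tumor, sub[[mcol]], col = cols[g], type = "b", pch = 16)
    se <- sub[[scol]]
    has_se <- !is.na(se) & se > 0
    if (any(has_se)) {
      graphics::arrows(sub$c_tumor[has_se], sub[[mcol]][has_se] - se[has_se],
                       sub$c_tumor[has_se], sub[[mcol]][has_se] + se[has_se],
                       angle = 90, code = 3, length = 0.03, col = cols[g])
    }
  }
  graphics::legend("topleft", legend = levels(grp), col = cols, lty = 1, pch = 16,
                   cex = 0.8, bty = "n")
  invisible(x)
}

#' Metric grid across labeled images (systems x backgrounds x methods)
#'
#' Computes both segmentation methods' metrics for a set of labeled images
#' and lays them out as one row per (phantom, background, system) with one
#' column per (metric, method) pair — the standard sensitivity-metric
#' comparison grid for imaging systems. Values are kept at full precision;
#' use [format_metric_grid()] for 2-significant-figure rendering.
#'
#' @param entries List of `list(image, phantom, background, system,
#'   truth = NULL)` entries; the (phantom, background, system) label triples
#'   must be unique.
#' @param roi_diameter_mm Circle-ROI diameter (default 5 mm).
#' @param background Background source for the circle ROI (see
#'   [concentration_sweep()]).
#' @param ... Otsu parameters passed through to [otsu_bands()].
#' @return A `data.frame` with label columns and
#'   `<metric>_otsu` / `<metric>_circle` value columns (NA where a region or
#'   metric was undefined, with reasons in `note`).
#' @export
metric_grid <- function(entries, roi_diameter_mm = 5,
                        background = c("otsu", "truth"), ...) {
  if (length(entries) == 0L) stop_nir("invalid_parameter", "no labeled images")
  background <- match.arg(background)
  labels <- vapply(entries, function(e)
    paste(e$phantom, e$background, e$system, sep = "|"), "")
  if (anyDuplicated(labels)) {
    stop_nir("labeling", "duplicate (phantom, background, system) labels: %s",
             labels[duplicated(labels)][1])
  }
  rows <- lapply(entries, function(e) {
    a <- analyze_one(e$image, e$truth, roi_diameters_mm = roi_diameter_mm,
                     background = background,
                     source = paste(e$phantom, e$background, e$system, sep = "/"), ...)
    row <- list(phantom = e$phantom, background = e$background, system = e$system)
    circle_key <- sprintf("circle_roi_%g", roi_diameter_mm)
    for (m in metric_names) {
      row[[paste0(m, "_otsu")]] <-
        if (!is.null(a$results$otsu_bands)) a$results$otsu_bands[[m]] else NA_real_
      row[[paste0(m, "_circle")]] <-
        if (!is.null(a$results[[circle_key]])) a$results[[circle_key]][[m]] else NA_real_
    }
    row$note <- if (length(a$failures))
      paste(names(a$failures), unlist(a$failures), sep = ": ", collapse = "; ") else ""
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' Render a metric grid at 2 significant figures
#'
#' Formatting happens only at render time; the pipeline itself never rounds.
#' Undefined cells render as `"--"`.
#'
#' @param grid Output of [metric_grid()].
#' @param digits Significant figures (default 2).
#' @return A character `data.frame` of the same shape.
#' @export
format_metric_grid <- function(grid, digits = 2) {
  out <- grid
  num <- vapply(out, is.numeric, TRUE)
  for (j in which(num)) {
    out[[j]] <- ifelse(is.na(grid[[j]]), "--",
                       trimws(format(signif(grid[[j]], digits))))
  }
  out
}
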