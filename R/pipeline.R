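# Batch entry points behind the command-line tool: simulate, analyze, series.
# Each writes reproducible outputs stamped with the package version and a
# config fingerprint; per-image failures are logged and collected, never
# fatal to the batch.

run_stamp <- function(config) {
  list(package = "nirphantom",
       version = as.character(utils::packageVersion("nirphantom")),
       config_hash = config_hash(config))
}

#' Validate and complete a run configuration
#'
#' Fills defaults (the standard analysis parameters: tumor factor 1.5,
#' background band 0.1--0.7, 256 Otsu bins, 5 mm ROI) and validates types and
#' ranges before any processing. Accepts a list, or a path to a JSON or YAML
#' config file.
#'
#' @param config Named list or file path. Recognized fields: `px_per_mm`
#'   (required, > 0), `profile` (`"research"`/`"clinical"` or a
#'   [system_profile()] field list), `tumor_factor`, `bg_low`, `bg_high`,
#'   `otsu_bins`, `roi_diameters_mm`, `normalize_after_crop`, `crop_boxes`
#'   (named list of `c(row0, col0, height, width)` per file name), `seed`.
#' @return The completed config list, of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yml", "yaml")) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop_nir("schema", "YAML config requires the yaml package; use JSON")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop_nir("schema", "config must be a list or a config file path")
  defaults <- list(tumor_factor = 1.5, bg_low = 0.1, bg_high = 0.7,
                   otsu_bins = 256L, roi_diameters_mm = 5,
                   normalize_after_crop = FALSE, profile = "research",
                   crop_boxes = NULL, seed = 1L)
  for (k in names(defaults)) config[[k]] <- config[[k]] %||% defaults[[k]]
  if (is.null(config$px_per_mm)) stop_nir("schema", "config is missing px_per_mm")
  check_number(config$px_per_mm, "px_per_mm", min = 0, strict_min = TRUE)
  check_number(config$tumor_factor, "tumor_factor", min = 0, strict_min = TRUE)
  if (!(0 < config$bg_low && config$bg_low < config$bg_high &&
        config$bg_high < config$tumor_factor)) {
    stop_nir("schema", "need 0 < bg_low < bg_high < tumor_factor")
  }
  check_number(as.numeric(config$otsu_bins), "otsu_bins", min = 2)
  check_number(config$roi_diameters_mm, "roi_diameters_mm", min = 0,
               strict_min = TRUE, len = length(config$roi_diameters_mm))
  if (is.character(config$profile)) {
    config$profile_obj <- system_profile(config$profile)
  } else if (inherits(config$profile, "system_profile")) {
    config$profile_obj <- config$profile
    config$profile <- config$profile$name
  } else {
    config$profile_obj <- do.call(system_profile, config$profile)
    config$profile <- config$profile_obj$name
  }
  structure(config, class = c("run_config", "list"))
}

serializable_config <- function(config) {
  config$profile_obj <- NULL
  class(config) <- "list"
  config
}

#' Analyze a batch of fluorescence images
#'
#' Loads each image, optionally crops it to the configured box, segments it
#' with both methods and computes the four sensitivity metrics, writing a
#' tidy CSV (one row per image x method x ROI), a JSON manifest with the
#' config, its fingerprint and per-image status, and (optionally) QC mask
#' overlays. A failing image is logged and skipped; the run continues.
#'
#' @param paths Character vector of image files (TIFF/PNG).
#' @param config A [run_config()] (or list / config file path).
#' @param out_dir Output directory (created if needed).
#' @param overlays Write mask-outline QC overlays per image (default FALSE).
#' @return Invisibly, a list with `metrics` (the data.frame written to CSV),
#'   `failures` (named list of error messages), `csv`, `manifest`.
#' @export
run_analyze <- function(paths, config, out_dir, overlays = FALSE) {
  config <- run_config(config)
  if (length(paths) == 0L) stop_nir("usage", "no input images")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  failures <- list()
  status <- list()
  for (p in paths) {
    res <- tryCatch({
      img <- load_image(p, config$profile_obj, config$px_per_mm)
      box <- config$crop_boxes[[basename(p)]]
      if (!is.null(box)) {
        img <- crop_to_phantom(img, box)
        if (isTRUE(config$normalize_after_crop)) {
          img$pixels <- normalize_to_unit(img$pixels)
        }
      }
      a <- analyze_one(img, methods = c("otsu_bands", "circle_roi"),
                       roi_diameters_mm = config$roi_diameters_mm,
                       background = "otsu",
                       tumor_factor = config$tumor_factor,
                       bg_low = config$bg_low, bg_high = config$bg_high,
                       bins = config$otsu_bins, source = basename(p))
      if (overlays) {
        for (key in names(a$results)) {
          m <- a$results[[key]]
          masks <- masks_from_params(img, list(method = m$method, params = m$params))
          save_overlay(img, masks,
                       file.path(out_dir, sprintf("%s_%s_overlay.png",
                                                  tools::file_path_sans_ext(basename(p)), key)))
        }
      }
      a
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[basename(p)]] <- conditionMessage(res)
      status[[basename(p)]] <- list(ok = FALSE, error = conditionMessage(res))
      next
    }
    for (key in names(res$results)) {
      rows[[length(rows) + 1L]] <- as.data.frame(res$results[[key]])
    }
    for (key in names(res$failures)) {
      failures[[paste(basename(p), key, sep = ":")]] <- res$failures[[key]]
    }
    status[[basename(p)]] <- list(ok = TRUE,
                                  n_results = length(res$results),
                                  n_failures = length(res$failures))
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image = character(), method = character(), roi_mm = numeric(),
               sbr = numeric(), snr = numeric(), cnr = numeric(), cvr = numeric())
  csv <- file.path(out_dir, "metrics.csv")
  utils::write.csv(metrics, csv, row.names = FALSE)
  manifest <- file.path(out_dir, "analyze_manifest.json")
  jsonlite::write_json(list(stamp = run_stamp(serializable_config(config)),
                            config = serializable_config(config),
                            images = status, failures = failures),
                       manifest, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(metrics = metrics, failures = failures, csv = csv,
                 manifest = manifest))
}

spec_to_list <- function(spec) {
  list(tumor = if (spec$tumor$type == "ellipse") spec$tumor[c("type", "center_mm",
                                                              "semi_axes_mm", "rotation_deg")]
       else list(type = "raster"),
       tumor_depth = spec$tumor_depth, c_tumor = spec$c_tumor,
       c_background = spec$c_background,
       optics = unclass(spec$optics)[c("mu_a", "mu_s_prime")],
       blur_sigma = spec$blur_sigma,
       field_inhomogeneity_amplitude = spec$field_inhomogeneity_amplitude,
       noise = unclass(spec$noise)[c("read_noise_sd", "shot_noise_gain")],
       system = unclass(spec$system),
       image_shape = spec$image_shape, px_per_mm = spec$px_per_mm,
       seed = spec$seed)
}

#' Read a phantom spec from a JSON sidecar
#'
#' Inverse of the sidecar written by [run_simulate()]. Validates the schema
#' before constructing the spec.
#'
#' @param path JSON file path, or an equivalent list.
#' @return A [phantom_spec()].
#' @export
phantom_spec_from_json <- function(path) {
  x <- if (is.character(path)) jsonlite::fromJSON(path) else path
  required <- c("tumor", "c_tumor", "c_background", "px_per_mm", "image_shape")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop_nir("schema", "phantom spec missing field(s): %s",
             paste(missing, collapse = ", "))
  }
  if (identical(x$tumor$type, "raster")) {
    stop_nir("schema", "raster tumor geometries cannot be rebuilt from a JSON sidecar")
  }
  phantom_spec(
    tumor = tumor_ellipse(as.numeric(x$tumor$center_mm),
                          as.numeric(x$tumor$semi_axes_mm),
                          x$tumor$rotation_deg %||% 0),
    tumor_depth = x$tumor_depth %||% 0,
    c_tumor = x$c_tumor, c_background = x$c_background,
    optics = optical_properties(x$optics$mu_a %||% 0.005,
                                x$optics$mu_s_prime %||% 1.06),
    blur_sigma = x$blur_sigma %||% 0,
    field_inhomogeneity_amplitude = x$field_inhomogeneity_amplitude %||% 0,
    noise = noise_model(x$noise$read_noise_sd %||% 0,
                        x$noise$shot_noise_gain %||% 0),
    system = if (is.null(x$system)) system_profile("research") else
      system_profile(x$system$name %||% "custom",
                     bit_depth = x$system$bit_depth,
                     channels = x$system$channels,
                     auto_gain = x$system$auto_gain,
                     grayscale_weights = x$system$grayscale_weights %||%
                       c(0.2126, 0.7152, 0.0722)),
    image_shape = as.integer(x$image_shape), px_per_mm = x$px_per_mm,
    seed = x$seed %||% 1L
  )
}

write_phantom_files <- function(gen, spec, out_dir, stem) {
  img_path <- if (spec$system$channels == "rgb") {
    p <- file.path(out_dir, paste0(stem, ".png"))
    arr <- array(rep(gen$image$pixels, 3), dim = c(dim(gen$image$pixels), 3))
    png::writePNG(arr, p)
    p
  } else {
    p <- file.path(out_dir, paste0(stem, ".tif"))
    tiff::writeTIFF(gen$image$pixels, p, bits.per.sample = 16L)
    p
  }
  write_mask(gen$truth$tumor_mask, file.path(out_dir, paste0(stem, "_tumor_mask.png")))
  write_mask(gen$truth$background_mask,
             file.path(out_dir, paste0(stem, "_background_mask.png")))
  jsonlite::write_json(spec_to_list(spec), file.path(out_dir, paste0(stem, "_spec.json")),
                       auto_unbox = TRUE, digits = NA)
  img_path
}

#' Simulate phantom images to disk
#'
#' Generates a single phantom image, or a replicated concentration series,
#' and writes per-image raster files (16-bit grayscale TIFF for grayscale
#' profiles, lossless 8-bit RGB PNG for RGB profiles), ground-truth masks as
#' black/white PNGs, JSON spec sidecars, and a manifest listing every output
#' and the seed. Identical specs produce identical files.
#'
#' @param spec A [phantom_spec()], or a path to a spec JSON.
#' @param out_dir Output directory.
#' @param concentrations If non-NULL, generate a series over these tumor
#'   concentrations instead of a single image.
#' @param replicates Replicates per concentration for a series (default 3).
#' @return Invisibly, the manifest list (also written as
#'   `simulate_manifest.json`).
#' @export
run_simulate <- function(spec, out_dir, concentrations = NULL, replicates = 3L) {
  if (is.character(spec) || (is.list(spec) && !inherits(spec, "phantom_spec"))) {
    spec <- phantom_spec_from_json(spec)
  }
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  if (is.null(concentrations)) {
    gen <- generate_phantom_image(spec)
    files <- write_phantom_files(gen, spec, out_dir, "phantom")
  } else {
    series <- generate_concentration_series(spec, concentrations, replicates,
                                            seed = spec$seed)
    for (s in series) {
      stem <- sprintf("phantom_c%s_r%d",
                      gsub("[.]", "p", format(s$condition$c_tumor)),
                      s$condition$replicate)
      sp <- spec
      sp$c_tumor <- s$condition$c_tumor
      files <- c(files, write_phantom_files(s, sp, out_dir, stem))
    }
  }
  manifest <- list(stamp = run_stamp(spec_to_list(spec)), seed = spec$seed,
                   images = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "simulate_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run a full concentration-series study
#'
#' Generates (or accepts) a replicated concentration series, sweeps both
#' segmentation methods and all requested ROI sizes over it, and writes the
#' summary table (CSV + JSON) and a metric-vs-concentration figure with
#' standard-error bars.
#'
#' @param x A [phantom_spec()] used as the series base, or an existing series
#'   list from [generate_concentration_series()].
#' @param out_dir Output directory.
#' @param concentrations Tumor concentrations (default 0.03, 0.1, 0.3, 1 uM).
#' @param replicates Replicates per concentration (default 3).
#' @param roi_diameters_mm Circle-ROI diameters (default `c(5, 7.5, 10)`).
#' @param background Circle-ROI background source (see
#'   [concentration_sweep()]).
#' @param plot_metric Metric plotted to `sweep_<metric>.png` (default "sbr";
#'   NULL disables).
#' @return Invisibly, the `concentration_sweep` table.
#' @export
run_series <- function(x, out_dir, concentrations = c(0.03, 0.1, 0.3, 1),
                       replicates = 3L, roi_diameters_mm = c(5, 7.5, 10),
                       background = "otsu", plot_metric = "sbr") {
  series <- if (inherits(x, "phantom_spec")) {
    generate_concentration_series(x, concentrations, replicates, seed = x$seed)
  } else {
    if (length(x) == 0L) stop_nir("usage", "empty input series")
    x
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sweep <- concentration_sweep(series, roi_diameters_mm = roi_diameters_mm,
                               background = background)
  utils::write.csv(sweep, file.path(out_dir, "sweep.csv"), row.names = FALSE)
  jsonlite::write_json(sweep, file.path(out_dir, "sweep.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  if (!is.null(plot_metric)) {
    grDevices::png(file.path(out_dir, sprintf("sweep_%s.png", plot_metric)),
                   width = 900, height = 650, res = 120)
    tryCatch(plot(sweep, metric = plot_metric), finally = grDevices::dev.off())
  }
  invisible(sweep)
}

#' Write a QC overlay of mask outlines on the image
#'
#' Grayscale base with the tumor-region outline in red and the background
#' region outline in blue, for visual checking of the segmentation.
#'
#' @param image A [calibrated_image()].
#' @param masks A [region_masks()].
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
save_overlay <- function(image, masks, path) {
  outline <- function(m) {
    er <- as.matrix(EBImage::erode(EBImage::Image(m * 1), EBImage::makeBrush(3, "box"))) > 0
    m & !er
  }
  base <- image$pixels
  arr <- array(rep(base, 3), dim = c(dim(base), 3))
  tum <- outline(masks$tumor_mask)
  bg <- outline(masks$background_mask)
  r <- arr[, , 1]; g <- arr[, , 2]; b <- arr[, , 3]
  r[tum] <- 1; g[tum] <- 0; b[tum] <- 0
  r[bg] <- 0; g[bg] <- 0.4; b[bg] <- 1
  arr[, , 1] <- r; arr[, , 2] <- g; arr[, , 3] <- b
  png::writePNG(arr, path)
  invisible(path)
}
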