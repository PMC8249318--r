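#' Pipeline configuration
#'
#' Validates the configuration for [run_pipeline()].  The pipeline accepts
#' either an in-memory [render_campaign()] object (`campaign`) or on-disk
#' inputs (`raster_paths` + `dates` + `polygon_path`).  Exactly one NDYI
#' threshold applies to the whole campaign (site-year), as in field practice.
#'
#' @param threshold flowering threshold value in (-1, 1) (required).
#' @param campaign optional in-memory `campaign`; its truth tables also
#'   provide the ground reference unless one is given explicitly.
#' @param raster_paths character vector of multi-page reflectance TIFFs, one
#'   per date (ignored when `campaign` is given).
#' @param dates Julian dates of `raster_paths`, same order.
#' @param polygon_path GeoJSON of plot polygons (pixel coordinates, or world
#'   coordinates with `geotransform`).
#' @param geotransform optional GDAL-style 6-vector for `polygon_path`.
#' @param manual_counts_path,yield_path optional ground-reference CSVs.
#' @param out_dir output directory for the stage CSVs and manifest.
#' @param tolerance manual-count date-matching tolerance, days.
#' @param indices index maps to compute (NDYI is always included; the
#'   flowering extraction runs on NDYI).
#' @param screening run the per-date yield screening layer.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold,
                            campaign = NULL,
                            raster_paths = NULL, dates = NULL,
                            polygon_path = NULL, geotransform = NULL,
                            manual_counts_path = NULL, yield_path = NULL,
                            out_dir = tempfile("flowerpheno_run_"),
                            tolerance = 4,
                            indices = "NDYI",
                            screening = TRUE) {
  spec <- threshold_spec(threshold)  # validation-first: fails before any IO
  if (is.null(campaign)) {
    if (is.null(raster_paths) || is.null(dates) || is.null(polygon_path))
      .stop2("either a campaign or raster_paths + dates + polygon_path is required")
    if (length(raster_paths) != length(dates))
      .stop2("raster_paths and dates must have equal length")
    missing <- raster_paths[!file.exists(raster_paths)]
    if (length(missing)) .stop2("raster not found: ", paste(missing, collapse = ", "))
    if (!file.exists(polygon_path)) .stop2("polygons not found: ", polygon_path)
  }
  indices <- union("NDYI", indices)
  bad <- setdiff(indices, names(INDEX_BANDS))
  if (length(bad)) .stop2("unknown index name(s): ", paste(bad, collapse = ", "))
  structure(list(threshold = spec, campaign = campaign,
                 raster_paths = raster_paths, dates = dates,
                 polygon_path = polygon_path, geotransform = geotransform,
                 manual_counts_path = manual_counts_path,
                 yield_path = yield_path, out_dir = out_dir,
                 tolerance = tolerance, indices = indices,
                 screening = isTRUE(screening)),
            class = "pipeline_config")
}

# Configuration digest for the manifest: hash of the deterministic textual
# form of the config (in-memory campaign represented by its own config).
.config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL  # output location is not part of the analysis identity
  if (!is.null(x$campaign)) x$campaign <- unclass(x$campaign$config)
  x$threshold <- unclass(x$threshold)
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(x, f)
  unname(tools::md5sum(f))
}

#' Run the full flowering-phenotyping pipeline
#'
#' Composes the stages end to end: load imagery and plot polygons, compute
#' NDYI maps, threshold and count flowering pixels per plot and date,
#' integrate each plot's series into AUFPC, and fit the calibration layers
#' (per-date zero-intercept count calibration where manual counts are
#' available; per-date yield screening and the yield-on-AUFPC regression
#' where yields are available).  Stage outputs are written as CSVs with a
#' manifest recording the configuration hash and package version; rerunning
#' an identical configuration reproduces byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @return A list with `counts`, `aufpc`, `fits` data frames, `series`
#'   (per-plot [flowering_series()]), `paths` of the written files, and
#'   `log` (character vector of per-stage messages, including dropped
#'   plots).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$campaign)) {
    images <- config$campaign$images
    plots <- config$campaign$plots
    ref <- ground_reference(
      manual_counts = if (is.null(config$manual_counts_path))
        config$campaign$truth$manual_counts
      else .read_csv(config$manual_counts_path,
                     c("plot_id", "date_julian", "manual_count")),
      yield = if (is.null(config$yield_path)) config$campaign$truth$yield
              else .read_csv(config$yield_path, c("plot_id", "yield")))
  } else {
    images <- mapply(function(p, d)
      read_reflectance_stack(p, stats::setNames(1:5, BAND_NAMES), d),
      config$raster_paths, config$dates, SIMPLIFY = FALSE)
    plots <- load_plot_polygons(config$polygon_path, config$geotransform)
    ref <- read_ground_reference(config$manual_counts_path, config$yield_path)
  }
  note("loaded ", length(images), " date(s), ", length(plots), " plot(s)")

  maps <- lapply(images, compute_index, name = "NDYI")
  series <- build_flowering_series(maps, plots, config$threshold)
  note("extracted flowering counts at threshold NDYI > ",
       config$threshold$value)

  counts <- do.call(rbind, lapply(seq_along(series), function(i) {
    s <- series[[i]]
    valid <- vapply(s$t, function(d) {
      m <- maps[[match(d, vapply(maps, `[[`, numeric(1), "date"))]]
      inside <- .plot_pixel_mask(dim(m$values), plots[[i]])
      sum(inside & !m$invalid)
    }, numeric(1))
    data.frame(plot_id = s$plot_id, date_julian = s$t,
               flower_pixels = s$count, valid_pixels = valid,
               threshold = config$threshold$value)
  }))

  batch <- compute_aufpc_batch(series)
  if (nrow(batch$errors))
    for (i in seq_len(nrow(batch$errors)))
      note("AUFPC skipped for ", batch$errors$plot_id[i], ": ",
           batch$errors$message[i])
  aufpc <- aufpc_table(batch)

  fits <- list()
  cal_fits <- list()
  if (!is.null(ref$manual_counts)) {
    for (d in sort(unique(counts$date_julian))) {
      fit <- tryCatch(
        calibrate_counts_by_date(series, ref, d, config$tolerance),
        error = function(e) e)
      if (inherits(fit, "error")) {
        note("count calibration skipped at day ", d, ": ",
             conditionMessage(fit))
      } else {
        cal_fits[[as.character(d)]] <- fit
        fits[[length(fits) + 1L]] <- data.frame(
          layer = "count_calibration", date_or_aufpc = d, slope = fit$slope,
          intercept = 0, r_squared = fit$r_squared, n = fit$n,
          sig_class = .sig_class(fit$p_value))
      }
    }
  } else note("no manual counts: count calibration skipped")

  if (!is.null(ref$yield)) {
    if (config$screening) {
      sc <- screen_dates_vs_yield(series, ref)
      fits[[length(fits) + 1L]] <- data.frame(
        layer = "yield_screen", date_or_aufpc = sc$date_julian,
        slope = sc$slope, intercept = sc$intercept,
        r_squared = sc$r_squared, n = sc$n, sig_class = sc$sig_class)
    }
    yfit <- tryCatch(yield_vs_aufpc(aufpc, ref), error = function(e) e)
    if (inherits(yfit, "error")) {
      note("yield-vs-AUFPC skipped: ", conditionMessage(yfit))
      yfit <- NULL
    } else {
      fits[[length(fits) + 1L]] <- data.frame(
        layer = "yield_aufpc", date_or_aufpc = NA_real_, slope = yfit$slope,
        intercept = yfit$intercept, r_squared = yfit$r_squared, n = yfit$n,
        sig_class = .sig_class(yfit$p_value))
    }
  } else {
    note("no yield table: yield layers skipped")
    yfit <- NULL
  }
  fits <- if (length(fits)) do.call(rbind, fits)
          else data.frame(layer = character(), date_or_aufpc = numeric(),
                          slope = numeric(), intercept = numeric(),
                          r_squared = numeric(), n = integer(),
                          sig_class = character())

  paths <- c(counts = file.path(config$out_dir, "counts.csv"),
             aufpc = file.path(config$out_dir, "aufpc.csv"),
             fits = file.path(config$out_dir, "fits.csv"),
             manifest = file.path(config$out_dir, "manifest.txt"),
             log = file.path(config$out_dir, "run.log"))
  names(aufpc)[names(aufpc) == "t_first"] <- "t_first"
  .write_csv(counts, paths[["counts"]])
  .write_csv(aufpc, paths[["aufpc"]])
  .write_csv(fits, paths[["fits"]])
  writeLines(c(paste0("flowerpheno_version: ",
                      as.character(utils::packageVersion("flowerpheno"))),
               paste0("config_md5: ", .config_hash(config)),
               paste0("threshold: ", config$threshold$value)),
             paths[["manifest"]])
  writeLines(log, paths[["log"]])

  list(counts = counts, aufpc = aufpc, fits = fits, series = series,
       calibration_fits = cal_fits, yield_fit = yfit, paths = paths,
       log = log)
}

#' Render scatter-and-fit report figures from a fits table
#'
#' Draws, as PNG files, the count-calibration scatter per date and the
#' yield-vs-AUFPC scatter, each with its fitted line — the standard
#' presentation of the two calibration layers.
#'
#' @param result a [run_pipeline()] result (needs `series`, `fits`, and a
#'   `yield_fit` when present).
#' @param dir output directory for the PNGs.
#' @return Character vector of written files, invisibly.
#' @export
report_figures <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  if (!is.null(result$yield_fit)) {
    f <- file.path(dir, "yield_vs_aufpc.png")
    grDevices::png(f, width = 700, height = 500)
    plot(result$yield_fit, xlab = "AUFPC (pixel-days)",
         ylab = "seed yield", main = sprintf(
           "y = %.4gx + %.4g, R^2 = %.2f", result$yield_fit$slope,
           result$yield_fit$intercept, result$yield_fit$r_squared))
    grDevices::dev.off()
    written <- c(written, f)
  }
  for (d in names(result$calibration_fits)) {
    fit <- result$calibration_fits[[d]]
    f <- file.path(dir, sprintf("calibration_day%03d.png",
                                round(as.numeric(d))))
    grDevices::png(f, width = 700, height = 500)
    plot(fit, xlab = "flowering pixels", ylab = "manual flower count",
         main = sprintf("day %s: y = %.3gx, R^2 = %.2f", d, fit$slope,
                        fit$r_squared))
    grDevices::dev.off()
    written <- c(written, f)
  }
  invisible(written)
}
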