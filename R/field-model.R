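#' Multi-band reflectance image for one acquisition date
#'
#' Container for a co-registered five-band (blue, green, red, red-edge, NIR)
#' reflectance grid from a single UAV flight, after upstream orthomosaicking
#' and radiometric calibration.  Reflectance is unitless, nominally in
#' \[0, 1\]; slightly out-of-range values from calibration artifacts are kept
#' (not clipped) so that downstream thresholds are not silently biased.
#'
#' @param bands named list of five numeric matrices (names `blue`, `green`,
#'   `red`, `rededge`, `nir`), all the same dimension.
#' @param date acquisition date as a Julian day-of-year (> 0) within one
#'   growing season.
#' @param mask optional logical matrix, `TRUE` where a pixel carries no data;
#'   defaults to all-`FALSE`.  Non-finite band values are added to the mask.
#' @param pixel_size optional ground sampling distance of one pixel, in cm.
#'
#' @return An object of class `reflectance_image`.
#' @seealso [read_reflectance_stack()], [compute_index()]
#' @export
reflectance_image <- function(bands, date, mask = NULL, pixel_size = NULL) {
  if (!is.list(bands) || !setequal(names(bands), BAND_NAMES))
    .stop2("bands must be a named list with exactly: ",
           paste(BAND_NAMES, collapse = ", "))
  bands <- bands[BAND_NAMES]
  dims <- lapply(bands, dim)
  if (any(!vapply(bands, is.matrix, logical(1))))
    .stop2("each band must be a numeric matrix")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    .stop2("all bands must have the same shape")
  if (!is.numeric(date) || length(date) != 1L || !is.finite(date) || date <= 0)
    .stop2("date must be a positive Julian day-of-year")
  d <- dims[[1L]]
  if (is.null(mask)) mask <- matrix(FALSE, d[1L], d[2L])
  if (!is.logical(mask) || !identical(dim(mask), d))
    .stop2("mask must be a logical matrix with the band shape")
  for (b in bands) mask <- mask | !is.finite(b)
  if (any(vapply(bands, function(b) any(!is.finite(b[!mask])), logical(1))))
    .stop2("unmasked reflectance values must be finite")
  structure(
    list(bands = bands, date = date, mask = mask, pixel_size = pixel_size),
    class = "reflectance_image"
  )
}

#' @export
print.reflectance_image <- function(x, ...) {
  d <- dim(x$bands[[1L]])
  cat(sprintf(
    "<reflectance_image> day %s, %d x %d px, 5 bands, %d masked px%s\n",
    format(x$date), d[1L], d[2L], sum(x$mask),
    if (is.null(x$pixel_size)) "" else sprintf(", GSD %.3g cm", x$pixel_size)))
  invisible(x)
}

#' @export
dim.reflectance_image <- function(x) dim(x$bands[[1L]])

#' Read a five-band reflectance raster stack
#'
#' Reads either five single-band TIFF files or one multi-page TIFF into a
#' [reflectance_image()].  Float-sample TIFFs (the usual export from
#' photogrammetry software) are read as-is; integer-sample TIFFs written by
#' [write_reflectance_stack()] are decoded from the package's linear storage
#' encoding, in which a stored 0 marks nodata.
#'
#' Values outside the plausible reflectance range \[-0.1, 1.5\] are reported
#' via a message but retained.
#'
#' @param paths character vector of TIFF file paths: either length five
#'   (single-band files) or length one (multi-page file).
#' @param band_map named integer vector mapping each band name in
#'   `c("blue","green","red","rededge","nir")` to its file index (length-five
#'   `paths`) or page index (multi-page file).
#' @param date Julian day-of-year of the acquisition.
#' @param nodata optional sentinel value: float-sample pixels equal to it are
#'   masked.  Ignored for package-encoded integer files, which carry their own
#'   sentinel.
#' @param pixel_size optional ground sampling distance in cm.
#'
#' @return A `reflectance_image`.
#' @export
read_reflectance_stack <- function(paths, band_map, date, nodata = NULL,
                                   pixel_size = NULL) {
  if (!all(BAND_NAMES %in% names(band_map)))
    .stop2("band_map must name all of: ", paste(BAND_NAMES, collapse = ", "))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) .stop2("file not found: ", paste(missing, collapse = ", "))

  read_page <- function(path, all_pages = FALSE)
    tiff::readTIFF(path, all = all_pages, info = TRUE)

  if (length(paths) == 1L) {
    pages <- read_page(paths, all_pages = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (max(band_map[BAND_NAMES]) > length(pages))
      .stop2("band_map indexes page ", max(band_map), " but file has ",
             length(pages), " page(s)")
    raw <- lapply(BAND_NAMES, function(b) pages[[band_map[[b]]]])
  } else {
    if (max(band_map[BAND_NAMES]) > length(paths))
      .stop2("band_map indexes file ", max(band_map), " but only ",
             length(paths), " path(s) given")
    raw <- lapply(BAND_NAMES, function(b) read_page(paths[[band_map[[b]]]]))
  }
  names(raw) <- BAND_NAMES

  shapes <- vapply(raw, function(m) paste(dim(m)[1:2], collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L)
    .stop2("shape mismatch across bands: ", paste(unique(shapes), collapse = " vs "))

  mask <- NULL
  bands <- lapply(raw, function(m) {
    is_float <- identical(attr(m, "sample.format"), "float")
    m <- m[, , drop = TRUE]
    if (length(dim(m)) == 3L) m <- m[, , 1L]  # first channel of multi-sample pages
    if (is_float) {
      bad <- !is.finite(m) | (if (is.null(nodata)) FALSE else m == nodata)
    } else {
      bad <- m == 0
      m <- .decode_sample(m)
    }
    m[bad] <- NA_real_
    mask <<- if (is.null(mask)) bad else mask | bad
    m
  })

  n_out <- sum(vapply(bands, function(m)
    sum(!is.na(m) & (m < -0.1 | m > 1.5)), integer(1)))
  if (n_out > 0)
    message("read_reflectance_stack: ", n_out,
            " pixel value(s) outside [-0.1, 1.5] retained")
  for (b in BAND_NAMES) bands[[b]][mask] <- 0  # masked values are placeholders
  reflectance_image(bands, date, mask = mask, pixel_size = pixel_size)
}

#' Write a reflectance image as a multi-page TIFF
#'
#' Pages are stored in canonical band order (blue, green, red, rededge, nir)
#' using the package's linear 32-bit encoding; masked pixels become the
#' stored-zero nodata sentinel.  [read_reflectance_stack()] inverts this
#' losslessly to ~1e-9.
#'
#' @param image a `reflectance_image`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reflectance_stack <- function(image, path) {
  stopifnot(inherits(image, "reflectance_image"))
  pages <- lapply(image$bands, function(b) {
    if (any(b[!image$mask] < -1 | b[!image$mask] > 3))
      .stop2("values outside the storable range [-1, 3]")
    s <- .encode_sample(b)
    s[image$mask] <- 0
    s
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Field-plot boundary polygon in raster pixel coordinates
#'
#' A plot (one experimental unit of the trial) is delimited by a simple
#' polygon in 0-based (row, col) raster coordinates with pixel centers at
#' integer coordinates.  All zonal extraction uses pixel-center containment
#' against this polygon.
#'
#' @param plot_id unique plot identifier (string).
#' @param vertices numeric matrix with columns `row`, `col` (one vertex per
#'   row, open ring, >= 3 vertices); must be simple with positive area.
#' @param genotype optional genotype/line label.
#'
#' @return An object of class `plot_geometry`.
#' @export
plot_geometry <- function(plot_id, vertices, genotype = NULL) {
  if (!is.character(plot_id) || length(plot_id) != 1L || !nzchar(plot_id))
    .stop2("plot_id must be a non-empty string")
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L || !all(is.finite(vertices)))
    .stop2("vertices must be a finite n x 2 matrix with n >= 3")
  colnames(vertices) <- c("row", "col")
  if (.polygon_area(vertices[, 1L], vertices[, 2L]) <= 0)
    .stop2("degenerate polygon (zero area) for plot ", plot_id)
  if (.polygon_self_intersects(vertices[, 1L], vertices[, 2L]))
    .stop2("self-intersecting polygon for plot ", plot_id)
  structure(list(plot_id = plot_id, vertices = vertices, genotype = genotype),
            class = "plot_geometry")
}

#' @export
print.plot_geometry <- function(x, ...) {
  cat(sprintf("<plot_geometry> %s: %d vertices, area %.1f px^2%s\n",
              x$plot_id, nrow(x$vertices),
              .polygon_area(x$vertices[, 1L], x$vertices[, 2L]),
              if (is.null(x$genotype)) "" else paste0(" [", x$genotype, "]")))
  invisible(x)
}

# Invert a GDAL-style geotransform gt = (x0, dx, rx, y0, ry, dy) mapping
# (col, row) pixel-corner coordinates to world (x, y); returns pixel-center
# (row, col) coordinates for world points.
.world_to_pixel <- function(x, y, gt) {
  a <- matrix(c(gt[2L], gt[5L], gt[3L], gt[6L]), 2L, 2L)
  if (abs(det(a)) < .Machine$double.eps) .stop2("singular geotransform")
  p <- solve(a, rbind(x - gt[1L], y - gt[4L]))
  cbind(row = p[2L, ] - 0.5, col = p[1L, ] - 0.5)
}

.pixel_to_world <- function(row, col, gt) {
  cx <- col + 0.5; ry <- row + 0.5
  cbind(x = gt[1L] + cx * gt[2L] + ry * gt[3L],
        y = gt[4L] + cx * gt[5L] + ry * gt[6L])
}

#' Load plot polygons from GeoJSON
#'
#' Reads polygon features with a `plot_id` property (and optional `genotype`)
#' and converts their coordinates to raster pixel space.
#'
#' @param path GeoJSON file with `Polygon` features.
#' @param geotransform optional GDAL-style 6-vector `(x0, dx, rx, y0, ry, dy)`
#'   mapping pixel corners to world coordinates; when `NULL`, coordinates are
#'   taken to be pixel-space already (`x` = col, `y` = row).
#' @return A list of [plot_geometry()] objects with unique ids.
#' @export
load_plot_polygons <- function(path, geotransform = NULL) {
  if (!file.exists(path)) .stop2("file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features %||% .stop2("not a GeoJSON FeatureCollection: ", path)
  plots <- lapply(feats, function(f) {
    pid <- f$properties$plot_id %||% .stop2("feature without plot_id property")
    geom <- f$geometry
    if (!identical(geom$type, "Polygon"))
      .stop2("unsupported geometry type '", geom$type, "' for plot ", pid)
    ring <- geom$coordinates[[1L]]
    xy <- do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
    # GeoJSON rings are closed; drop the repeated last vertex
    if (nrow(xy) > 1L && all(xy[1L, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
    rc <- if (is.null(geotransform)) cbind(row = xy[, 2L], col = xy[, 1L])
          else .world_to_pixel(xy[, 1L], xy[, 2L], geotransform)
    plot_geometry(as.character(pid), rc, genotype = f$properties$genotype %||% NULL)
  })
  ids <- vapply(plots, `[[`, character(1), "plot_id")
  if (anyDuplicated(ids))
    .stop2("duplicate plot id(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  plots
}

#' Write plot polygons to GeoJSON
#'
#' Inverse of [load_plot_polygons()]; coordinates are written in world space
#' when a geotransform is given, else in pixel space.
#'
#' @inheritParams load_plot_polygons
#' @param plots list of `plot_geometry` objects.
#' @return `path`, invisibly.
#' @export
write_plot_polygons <- function(plots, path, geotransform = NULL) {
  feats <- lapply(plots, function(p) {
    v <- p$vertices
    xy <- if (is.null(geotransform)) cbind(v[, "col"], v[, "row"])
          else .pixel_to_world(v[, "row"], v[, "col"], geotransform)
    ring <- lapply(seq_len(nrow(xy)), function(i) c(xy[i, 1L], xy[i, 2L]))
    ring[[length(ring) + 1L]] <- ring[[1L]]
    props <- list(plot_id = p$plot_id)
    if (!is.null(p$genotype)) props$genotype <- p$genotype
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-plot flowering pixel time series
#'
#' Ordered observations of (Julian date, flowering-pixel count) for one plot:
#' the input to the AUFPC temporal integration.
#'
#' @param plot_id plot identifier.
#' @param t numeric vector of Julian dates, strictly increasing.
#' @param count numeric vector of non-negative flowering-pixel counts,
#'   same length as `t`.
#' @return An object of class `flowering_series`.
#' @seealso [compute_aufpc()], [build_flowering_series()]
#' @export
flowering_series <- function(plot_id, t, count) {
  if (!is.character(plot_id) || length(plot_id) != 1L)
    .stop2("plot_id must be a string")
  if (length(t) != length(count))
    .stop2("t and count must have equal length")
  if (length(t) && (any(!is.finite(t)) || any(diff(t) <= 0)))
    .stop2("dates must be finite and strictly increasing for plot ", plot_id)
  if (any(!is.finite(count)) || any(count < 0))
    .stop2("counts must be finite and non-negative for plot ", plot_id)
  structure(list(plot_id = plot_id, t = as.numeric(t), count = as.numeric(count)),
            class = "flowering_series")
}

#' @export
print.flowering_series <- function(x, ...) {
  cat(sprintf("<flowering_series> %s: %d dates (%s)\n", x$plot_id,
              length(x$t), paste(format(x$t), collapse = ", ")))
  invisible(x)
}

#' @export
length.flowering_series <- function(x) length(x$t)

#' Read and write flowering-series tables
#'
#' CSV round-trip of (plot_id, date_julian, flower_pixels) triples.  Within a
#' plot, rows must carry strictly increasing dates after sorting; duplicated
#' dates are an error.
#'
#' @param series list of [flowering_series()] objects.
#' @param path CSV file path.
#' @return `write_series_table` returns `path` invisibly;
#'   `read_series_table` returns a list of `flowering_series`.
#' @export
write_series_table <- function(series, path) {
  rows <- lapply(series, function(s)
    data.frame(plot_id = rep(s$plot_id, length(s$t)),
               date_julian = s$t, flower_pixels = s$count))
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(plot_id = character(), date_julian = numeric(),
                        flower_pixels = numeric())
  .write_csv(df, path)
}

#' @rdname write_series_table
#' @export
read_series_table <- function(path) {
  df <- .read_csv(path, c("plot_id", "date_julian", "flower_pixels"))
  if (!nrow(df)) return(list())
  out <- lapply(split(df, factor(df$plot_id, levels = unique(df$plot_id))),
                function(g) {
    g <- g[order(g$date_julian), , drop = FALSE]
    if (anyDuplicated(g$date_julian))
      .stop2("duplicated date for plot ", g$plot_id[1L], " in ", path)
    flowering_series(g$plot_id[1L], g$date_julian, g$flower_pixels)
  })
  unname(out)
}

#' Ground-reference data for a campaign
#'
#' Bundles the manually collected field data used by the calibration layers:
#' per-plot manual flower counts by date and per-plot seed yield.
#'
#' @param manual_counts data frame with columns `plot_id`, `date_julian`,
#'   `manual_count` (counts >= 0), or `NULL`.
#' @param yield data frame with columns `plot_id`, `yield` (>= 0, e.g.
#'   kg/ha), or `NULL`.
#' @return An object of class `ground_reference`.
#' @export
ground_reference <- function(manual_counts = NULL, yield = NULL) {
  if (!is.null(manual_counts)) {
    stopifnot(all(c("plot_id", "date_julian", "manual_count") %in% names(manual_counts)))
    if (any(manual_counts$manual_count < 0)) .stop2("manual counts must be >= 0")
  }
  if (!is.null(yield)) {
    stopifnot(all(c("plot_id", "yield") %in% names(yield)))
    if (any(yield$yield < 0)) .stop2("yields must be >= 0")
    if (anyDuplicated(yield$plot_id)) .stop2("duplicate plot id in yield table")
  }
  structure(list(manual_counts = manual_counts, yield = yield),
            class = "ground_reference")
}

#' Read ground-reference tables from CSV
#'
#' @param manual_counts_path CSV with `plot_id`, `date_julian`,
#'   `manual_count`; `NULL` to omit.
#' @param yield_path CSV with `plot_id`, `yield`; `NULL` to omit.
#' @return A [ground_reference()] object.
#' @export
read_ground_reference <- function(manual_counts_path = NULL, yield_path = NULL) {
  mc <- if (!is.null(manual_counts_path))
    .read_csv(manual_counts_path, c("plot_id", "date_julian", "manual_count"))
  yl <- if (!is.null(yield_path)) .read_csv(yield_path, c("plot_id", "yield"))
  ground_reference(manual_counts = mc, yield = yl)
}

#' @rdname read_ground_reference
#' @param ref a `ground_reference` object.
#' @param manual_counts_path,yield_path output CSV paths (`NULL` to skip).
#' @export
write_ground_reference <- function(ref, manual_counts_path = NULL,
                                   yield_path = NULL) {
  stopifnot(inherits(ref, "ground_reference"))
  if (!is.null(manual_counts_path) && !is.null(ref$manual_counts))
    .write_csv(ref$manual_counts, manual_counts_path)
  if (!is.null(yield_path) && !is.null(ref$yield))
    .write_csv(ref$yield, yield_path)
  invisible(ref)
}
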