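# Band pairs (A, B) of the four normalized-difference indices (A - B)/(A + B).
INDEX_BANDS <- list(
  NDVI  = c("nir", "red"),
  NDYI  = c("green", "blue"),
  GNDVI = c("nir", "green"),
  NDRE  = c("nir", "rededge")
)

#' Compute a normalized-difference vegetation index map
#'
#' Computes one of the four normalized-difference indices used to screen for
#' flowering signal:
#' \describe{
#'   \item{NDVI}{(NIR - red)/(NIR + red)}
#'   \item{NDYI}{(green - blue)/(green + blue), the yellowness index: canola
#'     petals absorb blue and reflect green, so open yellow flowers score
#'     high}
#'   \item{GNDVI}{(NIR - green)/(NIR + green)}
#'   \item{NDRE}{(NIR - rededge)/(NIR + rededge)}
#' }
#'
#' Pixels whose denominator is <= 0, whose inputs are masked, or whose value
#' falls outside \[-1, 1\] (possible only with negative reflectance inputs
#' from calibration noise) are flagged invalid, not zeroed: soil or shadow
#' must count neither as flowering nor as non-flowering downstream.
#'
#' @param image a [reflectance_image()].
#' @param name one of `"NDVI"`, `"NDYI"`, `"GNDVI"`, `"NDRE"`.
#' @return An object of class `index_map` with fields `index`, `values`
#'   (matrix, `NA` where invalid), `invalid` (logical matrix), `date`,
#'   `pixel_size`.
#' @examples
#' img <- reflectance_image(
#'   setNames(rep(list(matrix(0.3, 2, 2)), 5),
#'            c("blue", "green", "red", "rededge", "nir")), date = 190)
#' compute_index(img, "NDYI")$values  # 0 everywhere: green == blue
#' @export
compute_index <- function(image, name) {
  stopifnot(inherits(image, "reflectance_image"))
  if (!name %in% names(INDEX_BANDS))
    .stop2("unknown index '", name, "'; expected one of ",
           paste(names(INDEX_BANDS), collapse = ", "))
  ab <- INDEX_BANDS[[name]]
  a <- image$bands[[ab[1L]]]
  b <- image$bands[[ab[2L]]]
  denom <- a + b
  v <- (a - b) / denom
  invalid <- image$mask | !is.finite(denom) | denom <= 0 | !is.finite(v) |
    v < -1 | v > 1
  v[invalid] <- NA_real_
  structure(list(index = name, values = v, invalid = invalid,
                 date = image$date, pixel_size = image$pixel_size),
            class = "index_map")
}

#' @export
print.index_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<index_map> %s, day %s, %d x %d px, %d invalid px\n",
              x$index, format(x$date), d[1L], d[2L], sum(x$invalid)))
  invisible(x)
}

#' @export
dim.index_map <- function(x) dim(x$values)

# Logical matrix: TRUE where the pixel center lies inside the plot polygon.
# Restricted to the polygon's bounding box for speed.  Errors if the polygon
# lies entirely outside the raster extent.
.plot_pixel_mask <- function(shape, plot) {
  v <- plot$vertices
  r0 <- max(0L, ceiling(min(v[, "row"])))
  r1 <- min(shape[1L] - 1L, floor(max(v[, "row"])))
  c0 <- max(0L, ceiling(min(v[, "col"])))
  c1 <- min(shape[2L] - 1L, floor(max(v[, "col"])))
  out <- matrix(FALSE, shape[1L], shape[2L])
  if (max(v[, "row"]) < -0.5 || min(v[, "row"]) > shape[1L] - 0.5 ||
      max(v[, "col"]) < -0.5 || min(v[, "col"]) > shape[2L] - 0.5)
    .stop2("plot ", plot$plot_id, " lies outside the raster extent")
  if (r1 < r0 || c1 < c0) return(out)
  rows <- r0:r1; cols <- c0:c1
  pr <- rep(rows, times = length(cols))
  pc <- rep(cols, each = length(rows))
  inside <- .points_in_polygon(pr, pc, v[, "row"], v[, "col"])
  out[cbind(pr[inside] + 1L, pc[inside] + 1L)] <- TRUE
  out
}

#' Plot-level summary of an index map
#'
#' Zonal statistics of the valid index values whose pixel centers fall inside
#' the plot polygon.
#'
#' @param map an `index_map`.
#' @param plot a [plot_geometry()].
#' @return A list with `plot_id`, `mean`, `min`, `max`, `n_valid`,
#'   `n_pixels` (centers inside the polygon), and `defined` (`FALSE` when no
#'   valid pixel lies inside, in which case the statistics are `NA`).
#' @export
index_summary <- function(map, plot) {
  stopifnot(inherits(map, "index_map"), inherits(plot, "plot_geometry"))
  inside <- .plot_pixel_mask(dim(map$values), plot)
  vals <- map$values[inside & !map$invalid]
  if (!length(vals))
    return(list(plot_id = plot$plot_id, mean = NA_real_, min = NA_real_,
                max = NA_real_, n_valid = 0L, n_pixels = sum(inside),
                defined = FALSE))
  list(plot_id = plot$plot_id, mean = mean(vals), min = min(vals),
       max = max(vals), n_valid = length(vals), n_pixels = sum(inside),
       defined = TRUE)
}

#' Write or read a single-band index map TIFF
#'
#' Uses the package's linear 32-bit storage encoding; invalid pixels become
#' the nodata sentinel.  `read_index_map` inverts `write_index_map`.
#'
#' @param map an `index_map`.
#' @param path TIFF file path.
#' @param name index name of the stored map (`read_index_map`).
#' @param date Julian date of the stored map (`read_index_map`).
#' @return `write_index_map` returns `path` invisibly; `read_index_map`
#'   returns an `index_map`.
#' @export
write_index_map <- function(map, path) {
  stopifnot(inherits(map, "index_map"))
  s <- .encode_sample(map$values)
  s[map$invalid] <- 0
  tiff::writeTIFF(s, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_index_map
#' @export
read_index_map <- function(path, name, date) {
  if (!file.exists(path)) .stop2("file not found: ", path)
  if (!name %in% names(INDEX_BANDS)) .stop2("unknown index '", name, "'")
  s <- tiff::readTIFF(path)
  invalid <- s == 0
  v <- .decode_sample(s)
  v[invalid] <- NA_real_
  structure(list(index = name, values = v, invalid = invalid, date = date,
                 pixel_size = NULL),
            class = "index_map")
}
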