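#' Flowering-pixel threshold specification
#'
#' One NDYI threshold per campaign (site-year), as in field practice where the
#' cutoff is fixed per year (e.g. 0.59, 0.52 and 0.45 across three seasons).
#' Comparison is strictly greater-than: a pixel equal to the threshold is not
#' flowering.
#'
#' @param value threshold in (-1, 1).
#' @param index index name the threshold applies to (default `"NDYI"`).
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(value, index = "NDYI") {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= -1 || value >= 1)
    .stop2("threshold must be a single value in (-1, 1)")
  if (!index %in% names(INDEX_BANDS)) .stop2("unknown index '", index, "'")
  structure(list(value = value, index = index), class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold_spec> %s > %g\n", x$index, x$value))
  invisible(x)
}

#' Threshold an index map into a flowering mask
#'
#' A pixel is flowering iff it is valid and its index value is strictly
#' greater than the threshold; invalid pixels are always `FALSE`.
#'
#' @param map an `index_map` whose index matches `spec`.
#' @param spec a [threshold_spec()].
#' @return A logical matrix of the map's shape.
#' @export
threshold_mask <- function(map, spec) {
  stopifnot(inherits(map, "index_map"), inherits(spec, "threshold_spec"))
  if (!identical(map$index, spec$index))
    .stop2("threshold is for ", spec$index, " but map is ", map$index)
  m <- !map$invalid & map$values > spec$value
  m[is.na(m)] <- FALSE
  m
}

#' Count flowering pixels within a plot
#'
#' Zonal count of threshold-exceeding pixels whose centers lie inside the
#' plot polygon.
#'
#' @inheritParams threshold_mask
#' @param plot a [plot_geometry()] intersecting the map extent.
#' @return A non-negative integer count.
#' @export
count_flowering_pixels <- function(map, plot, spec) {
  mask <- threshold_mask(map, spec)
  inside <- .plot_pixel_mask(dim(mask), plot)
  sum(mask & inside)
}

#' Assemble per-plot flowering time series from dated index maps
#'
#' Runs [count_flowering_pixels()] for every plot on every map and collects
#' the counts into one [flowering_series()] per plot, dates ascending.  A
#' plot/date combination whose count cannot be computed (plot outside that
#' map's extent) is absent from the series, not zero-filled.
#'
#' @param maps list of `index_map` objects with distinct dates.
#' @param plots list of [plot_geometry()] objects.
#' @param spec a [threshold_spec()].
#' @return A list of `flowering_series`, one per plot, in plot order.
#' @export
build_flowering_series <- function(maps, plots, spec) {
  dates <- vapply(maps, `[[`, numeric(1), "date")
  if (anyDuplicated(dates))
    .stop2("duplicate acquisition date(s): ",
           paste(unique(dates[duplicated(dates)]), collapse = ", "))
  maps <- maps[order(dates)]
  dates <- sort(dates)
  lapply(plots, function(p) {
    t_obs <- numeric(); f_obs <- numeric()
    for (i in seq_along(maps)) {
      cnt <- tryCatch(count_flowering_pixels(maps[[i]], p, spec),
                      error = function(e) NA_integer_)
      if (!is.na(cnt)) {
        t_obs <- c(t_obs, dates[i])
        f_obs <- c(f_obs, cnt)
      }
    }
    flowering_series(p$plot_id, t_obs, f_obs)
  })
}

#' Suggest a flowering threshold from pooled index values
#'
#' A reproducible surrogate for the manual threshold choice (field practice
#' compares composited RGB images with the index maps by eye).  `"otsu"`
#' maximizes between-class variance over a 256-bin histogram of the pooled
#' valid values; `"quantile"` returns the type-1 (inverse-ECDF, no
#' interpolation) sample quantile at `q`.  Advisory only: the pipeline never
#' applies a suggested threshold implicitly.
#'
#' @param maps an `index_map` or list of them; valid pixels are pooled.
#' @param method `"otsu"` or `"quantile"`.
#' @param q quantile level for `method = "quantile"`.
#' @return A single threshold value within the observed value range.
#' @export
suggest_threshold <- function(maps, method = c("otsu", "quantile"), q = 0.9) {
  method <- match.arg(method)
  if (inherits(maps, "index_map")) maps <- list(maps)
  x <- unlist(lapply(maps, function(m) m$values[!m$invalid]), use.names = FALSE)
  if (length(unique(x)) < 2L)
    .stop2("need at least 2 distinct valid values to suggest a threshold")
  if (method == "quantile")
    return(unname(stats::quantile(x, q, type = 1L)))
  # Otsu on a fixed 256-bin histogram spanning the observed range
  breaks <- seq(min(x), max(x), length.out = 257L)
  h <- hist(x, breaks = breaks, plot = FALSE)
  n <- length(x)
  w <- cumsum(h$counts)
  m <- cumsum(h$counts * h$mids)
  mt <- m[256L]
  k <- 1:255
  w0 <- w[k] / n
  valid <- w[k] > 0 & w[k] < n
  mu0 <- m[k] / w[k]
  mu1 <- (mt - m[k]) / (n - w[k])
  bcv <- ifelse(valid, w0 * (1 - w0) * (mu0 - mu1)^2, -Inf)
  breaks[which.max(bcv) + 1L]
}
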