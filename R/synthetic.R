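#' Default spectral signatures for the synthetic field
#'
#' Per-class mean reflectance in the five bands plus a per-band Gaussian
#' noise sd.  Defaults put flower NDYI at 0.75 (yellow petals: strong green,
#' weak blue — carotenoids absorb blue) and leaf NDYI at 0.25, bracketing the
#' NDYI thresholds used in practice (0.45–0.59) so those serve as working
#' config examples.  The leaf green/blue levels are set high enough that
#' band noise of sd 0.02 keeps leaf NDYI about two standard deviations below
#' a 0.5 threshold.  The optional pod class sits at NDYI 0.50, emulating the
#' late-season dark-green pods that blur the flower/canopy separation.
#'
#' @param noise_sd per-band reflectance noise sd applied to every class
#'   (default 0.02).
#' @return Named list of classes (`flower`, `leaf`, `soil`, `pod`), each a
#'   list with `mean` (named 5-vector) and `sd` (named 5-vector).
#' @export
default_signatures <- function(noise_sd = 0.02) {
  mk <- function(blue, green, red, rededge, nir)
    list(mean = c(blue = blue, green = green, red = red,
                  rededge = rededge, nir = nir),
         sd = stats::setNames(rep(noise_sd, 5L), BAND_NAMES))
  list(flower = mk(0.05, 0.35, 0.25, 0.35, 0.45),
       leaf   = mk(0.09, 0.15, 0.06, 0.25, 0.45),
       soil   = mk(0.12, 0.15, 0.18, 0.22, 0.26),
       pod    = mk(0.06, 0.18, 0.10, 0.28, 0.40))
}

#' NDYI of a spectral signature's class means
#'
#' @param sig one class entry of [default_signatures()].
#' @return The noise-free NDYI of the class.
#' @export
signature_ndyi <- function(sig) {
  unname((sig$mean["green"] - sig$mean["blue"]) /
           (sig$mean["green"] + sig$mean["blue"]))
}

#' Unimodal flowering phenology curve
#'
#' Gaussian bell describing a genotype's flower fraction over the season:
#' `fraction(t) = amplitude * exp(-((t - peak)/width)^2 / 2)`.  Amplitude is
#' the peak fraction of plot pixels that are open flowers; width (days)
#' controls flowering duration (full width at half maximum is about
#' 2.35 * width, so widths of 6–12 days emulate the 2–6 week flowering
#' window of canola).
#'
#' @param amplitude peak flower fraction in \[0, 1\].
#' @param peak Julian day of peak flowering.
#' @param width curve sd in days (> 0).
#' @return An object of class `phenology_curve`.
#' @export
phenology_curve <- function(amplitude, peak, width) {
  if (!is.numeric(amplitude) || amplitude < 0 || amplitude > 1)
    .stop2("amplitude must be in [0, 1]")
  if (!is.numeric(width) || width <= 0) .stop2("width must be > 0")
  structure(list(amplitude = amplitude, peak = peak, width = width),
            class = "phenology_curve")
}

#' @rdname phenology_curve
#' @param curve a `phenology_curve`.
#' @param t Julian day(s).
#' @return `flowering_fraction` returns the flower fraction at `t`, in
#'   \[0, amplitude\].
#' @export
flowering_fraction <- function(curve, t) {
  stopifnot(inherits(curve, "phenology_curve"))
  curve$amplitude * exp(-0.5 * ((t - curve$peak) / curve$width)^2)
}

#' Synthetic campaign configuration
#'
#' Defines one simulated site-year: a grid of rectangular plots imaged on a
#' set of Julian dates, each plot a per-pixel mixture of flower/leaf/soil
#' (optionally pod) whose flower fraction follows a per-plot unimodal
#' phenology curve.  Defaults emulate a 50-plot trial flown weekly for seven
#' dates through the flowering window, with per-band sensor noise sd 0.02,
#' manual-count noise CV 10% and yield noise at 5% of the yield-signal
#' range.  The manual-count factor (1.6 actual flowers per flowering pixel)
#' and the yield model (intercept 1384.7, slope 0.0026 per pixel-day) are
#' realistic field-scale values.
#'
#' @param n_plots number of plots.
#' @param plot_rows,plot_cols plot size in pixels.
#' @param buffer soil buffer between plots, pixels.
#' @param dates strictly increasing Julian acquisition dates.
#' @param amplitude_range,peak_range,width_range ranges from which each
#'   plot's phenology parameters are drawn uniformly.
#' @param signatures class spectral signatures, see [default_signatures()].
#' @param noise_sd per-band reflectance noise sd; overrides the sds in
#'   `signatures` when not `NULL`.
#' @param leaf_fraction fraction of non-flower plot pixels that are canopy
#'   (the rest is within-plot soil).
#' @param manual_factor actual flowers per flowering pixel (the quantity the
#'   count calibration estimates).
#' @param manual_noise_cv multiplicative CV of the manual-count analog.
#' @param yield_b0,yield_b1 yield model: `yield = b0 + b1 * AUFPC_true + eps`.
#' @param yield_noise_frac sd of `eps` as a fraction of the range of
#'   `b1 * AUFPC_true` across plots.
#' @param pods enable the late-season pod class.
#' @param pod_max maximum pod share of the canopy, reached at the last date.
#' @param pixel_size ground sampling distance, cm.
#' @param seed master seed; a fixed seed makes [render_campaign()] fully
#'   deterministic and per-plot draws independent of plot order.
#' @return An object of class `campaign_config`.
#' @export
campaign_config <- function(n_plots = 50L,
                            plot_rows = 20L, plot_cols = 20L, buffer = 4L,
                            dates = seq(178, 220, by = 7),
                            amplitude_range = c(0.3, 0.8),
                            peak_range = c(190, 205),
                            width_range = c(6, 12),
                            signatures = default_signatures(),
                            noise_sd = 0.02,
                            leaf_fraction = 0.85,
                            manual_factor = 1.6,
                            manual_noise_cv = 0.10,
                            yield_b0 = 1384.70,
                            yield_b1 = 0.0026,
                            yield_noise_frac = 0.05,
                            pods = FALSE,
                            pod_max = 0.5,
                            pixel_size = 1.5,
                            seed = 1L) {
  if (any(diff(dates) <= 0) || length(dates) < 2L)
    .stop2("dates must be >= 2 and strictly increasing")
  if (n_plots < 1L) .stop2("n_plots must be >= 1")
  if (!setequal(names(signatures), c("flower", "leaf", "soil", "pod")))
    .stop2("signatures must define flower, leaf, soil, pod")
  if (!is.null(noise_sd))
    signatures <- lapply(signatures, function(s) {
      s$sd[] <- noise_sd; s
    })
  cfg <- list(n_plots = as.integer(n_plots), plot_rows = as.integer(plot_rows),
              plot_cols = as.integer(plot_cols), buffer = as.integer(buffer),
              dates = as.numeric(dates), amplitude_range = amplitude_range,
              peak_range = peak_range, width_range = width_range,
              signatures = signatures, leaf_fraction = leaf_fraction,
              manual_factor = manual_factor, manual_noise_cv = manual_noise_cv,
              yield_b0 = yield_b0, yield_b1 = yield_b1,
              yield_noise_frac = yield_noise_frac, pods = isTRUE(pods),
              pod_max = pod_max, pixel_size = pixel_size,
              seed = as.integer(seed))
  structure(cfg, class = "campaign_config")
}

# Plot-grid layout: returns per-plot top-left pixel (r0, c0) and scene shape.
.campaign_layout <- function(cfg) {
  ncols <- ceiling(sqrt(2 * cfg$n_plots))
  nrows <- ceiling(cfg$n_plots / ncols)
  k <- seq_len(cfg$n_plots) - 1L
  i <- k %/% ncols
  j <- k %% ncols
  list(r0 = cfg$buffer + i * (cfg$plot_rows + cfg$buffer),
       c0 = cfg$buffer + j * (cfg$plot_cols + cfg$buffer),
       shape = c(nrows * (cfg$plot_rows + cfg$buffer) + cfg$buffer,
                 ncols * (cfg$plot_cols + cfg$buffer) + cfg$buffer))
}

# Per-plot deterministic parameter draws (phenology + noise z-scores).
.plot_params <- function(cfg, k) {
  .with_seed(.substream_seed(cfg$seed, a = k), {
    list(curve = phenology_curve(
           stats::runif(1, cfg$amplitude_range[1L], cfg$amplitude_range[2L]),
           stats::runif(1, cfg$peak_range[1L], cfg$peak_range[2L]),
           stats::runif(1, cfg$width_range[1L], cfg$width_range[2L])),
         z_manual = stats::rnorm(length(cfg$dates)),
         z_yield = stats::rnorm(1))
  })
}

.pod_share <- function(cfg, curve, t) {
  if (!cfg$pods) return(0)
  t_last <- cfg$dates[length(cfg$dates)]
  if (t_last <= curve$peak) return(0)
  cfg$pod_max * min(1, max(0, (t - curve$peak) / (t_last - curve$peak)))
}

#' Render a synthetic campaign
#'
#' Generates the full site-year: one five-band [reflectance_image()] per
#' acquisition date, the plot polygons, and ground-truth tables.  Per plot
#' and date, each pixel is an open flower with probability given by the
#' plot's phenology curve; the remainder is canopy (leaf, or pod late in the
#' season when pods are enabled) and within-plot soil in fixed proportion.
#' Reflectance is the class mean plus Gaussian band noise, truncated at 0.
#'
#' Ground truth records, per plot: exact flower-pixel counts per date; a
#' manual-count analog `manual_factor * count * (1 + cv * z)` (kept numeric,
#' not rounded, so the noise-free analog is exactly proportional to the
#' counts); true AUFPC computed from the true counts; and yield
#' `b0 + b1 * AUFPC_true + eps`.
#'
#' All randomness derives from `config$seed` through per-plot and per-date
#' substreams, so output is reproducible and a plot's truth does not depend
#' on how many other plots are rendered after it.  The caller's RNG state is
#' left untouched.
#'
#' @param config a [campaign_config()].
#' @return An object of class `campaign`: list with `images` (per date),
#'   `plots` (list of [plot_geometry()]), `truth` (list of data frames
#'   `counts`, `manual_counts`, `aufpc`, `yield`, plus `yield_noise_sd`),
#'   and `config`.
#' @export
render_campaign <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  cfg <- config
  lay <- .campaign_layout(cfg)
  if (any(lay$r0 + cfg$plot_rows > lay$shape[1L]) ||
      any(lay$c0 + cfg$plot_cols > lay$shape[2L]))
    .stop2("inconsistent config: plots exceed scene")
  classes <- c("soil", "flower", "leaf", "pod")
  npx <- cfg$plot_rows * cfg$plot_cols

  params <- lapply(seq_len(cfg$n_plots), function(k) .plot_params(cfg, k))
  plot_ids <- sprintf("P%03d", seq_len(cfg$n_plots))
  plots <- lapply(seq_len(cfg$n_plots), function(k) {
    r0 <- lay$r0[k]; c0 <- lay$c0[k]
    plot_geometry(plot_ids[k], cbind(
      row = c(r0, r0, r0 + cfg$plot_rows, r0 + cfg$plot_rows) - 0.5,
      col = c(c0, c0 + cfg$plot_cols, c0 + cfg$plot_cols, c0) - 0.5),
      genotype = sprintf("line%03d", k))
  })

  counts <- matrix(0L, cfg$n_plots, length(cfg$dates))
  images <- vector("list", length(cfg$dates))
  for (d in seq_along(cfg$dates)) {
    t <- cfg$dates[d]
    cls <- matrix(1L, lay$shape[1L], lay$shape[2L])  # soil background
    for (k in seq_len(cfg$n_plots)) {
      p <- params[[k]]
      f <- flowering_fraction(p$curve, t)
      pod <- .pod_share(cfg, p$curve, t)
      u <- .with_seed(.substream_seed(cfg$seed, a = k, b = d, c = 1L),
                      stats::runif(npx))
      is_fl <- u < f
      # remainder rescaled to a fresh uniform for the canopy/soil split
      rem <- (u - f) / (1 - f)
      p_leaf <- cfg$leaf_fraction * (1 - pod)
      p_pod <- cfg$leaf_fraction * pod
      ck <- ifelse(is_fl, 2L, ifelse(rem < p_leaf, 3L,
                   ifelse(rem < p_leaf + p_pod, 4L, 1L)))
      rows <- lay$r0[k] + seq_len(cfg$plot_rows) - 1L
      cols <- lay$c0[k] + seq_len(cfg$plot_cols) - 1L
      cls[rows + 1L, cols + 1L] <- matrix(ck, cfg$plot_rows, cfg$plot_cols)
      counts[k, d] <- sum(is_fl)
    }
    bands <- .with_seed(.substream_seed(cfg$seed, a = 0L, b = d, c = 2L), {
      lapply(stats::setNames(BAND_NAMES, BAND_NAMES), function(b) {
        mu <- vapply(classes, function(cl) cfg$signatures[[cl]]$mean[[b]],
                     numeric(1))
        sd <- vapply(classes, function(cl) cfg$signatures[[cl]]$sd[[b]],
                     numeric(1))
        v <- mu[cls]
        if (any(sd > 0)) v <- v + stats::rnorm(length(v), 0, sd[cls])
        matrix(pmax(v, 0), lay$shape[1L], lay$shape[2L])
      })
    })
    images[[d]] <- reflectance_image(bands, t, pixel_size = cfg$pixel_size)
  }

  truth_counts <- data.frame(
    plot_id = rep(plot_ids, each = length(cfg$dates)),
    date_julian = rep(cfg$dates, cfg$n_plots),
    flower_pixels = as.vector(t(counts)))
  manual <- truth_counts
  names(manual)[3L] <- "manual_count"
  zs <- unlist(lapply(params, `[[`, "z_manual"))
  manual$manual_count <- pmax(
    0, cfg$manual_factor * truth_counts$flower_pixels *
      (1 + cfg$manual_noise_cv * zs))

  true_series <- lapply(seq_len(cfg$n_plots), function(k)
    flowering_series(plot_ids[k], cfg$dates, counts[k, ]))
  aufpc_truth <- aufpc_table(compute_aufpc_batch(true_series))

  signal <- cfg$yield_b1 * aufpc_truth$aufpc
  ysd <- cfg$yield_noise_frac * diff(range(signal))
  zy <- vapply(params, `[[`, numeric(1), "z_yield")
  yield <- data.frame(plot_id = plot_ids,
                      yield = pmax(0, cfg$yield_b0 + signal + ysd * zy))

  structure(list(images = images, plots = plots,
                 truth = list(counts = truth_counts, manual_counts = manual,
                              aufpc = aufpc_truth, yield = yield,
                              yield_noise_sd = ysd),
                 config = cfg),
            class = "campaign")
}

#' @export
print.campaign <- function(x, ...) {
  cat(sprintf(
    "<campaign> %d plots x %d dates (days %s-%s), scene %s px, seed %d\n",
    x$config$n_plots, length(x$config$dates), format(min(x$config$dates)),
    format(max(x$config$dates)),
    paste(dim(x$images[[1L]]), collapse = " x "), x$config$seed))
  invisible(x)
}

#' Write a campaign's ground truth as pipeline-schema CSVs
#'
#' Emits `truth_counts.csv` (plot_id, date_julian, flower_pixels),
#' `truth_aufpc.csv` (plot_id, aufpc, n_obs, t_first, t_last),
#' `manual_counts.csv` and `yield.csv`, column-compatible with the pipeline's
#' own outputs so truth and estimates diff columnwise.
#'
#' @param campaign a [render_campaign()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
truth_report <- function(campaign, dir) {
  stopifnot(inherits(campaign, "campaign"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "truth_counts.csv"),
             aufpc = file.path(dir, "truth_aufpc.csv"),
             manual_counts = file.path(dir, "manual_counts.csv"),
             yield = file.path(dir, "yield.csv"))
  .write_csv(campaign$truth$counts, paths[["counts"]])
  .write_csv(campaign$truth$aufpc, paths[["aufpc"]])
  .write_csv(campaign$truth$manual_counts, paths[["manual_counts"]])
  .write_csv(campaign$truth$yield, paths[["yield"]])
  invisible(paths)
}

#' Write a campaign's imagery and polygons to disk
#'
#' One multi-page reflectance TIFF per date plus a pixel-space GeoJSON of the
#' plot polygons — the on-disk form the file-composed pipeline consumes.
#'
#' @param campaign a [render_campaign()] result.
#' @param dir output directory.
#' @return List with `rasters` (named by date), `polygons`, `dates`.
#' @export
write_campaign <- function(campaign, dir) {
  stopifnot(inherits(campaign, "campaign"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rasters <- vapply(campaign$images, function(img) {
    p <- file.path(dir, sprintf("reflectance_day%03d.tif", round(img$date)))
    write_reflectance_stack(img, p)
    p
  }, character(1))
  poly <- file.path(dir, "plots.geojson")
  write_plot_polygons(campaign$plots, poly)
  list(rasters = rasters, polygons = poly,
       dates = vapply(campaign$images, `[[`, numeric(1), "date"))
}
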