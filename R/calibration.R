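.sig_class <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

.new_calibration_fit <- function(slope, intercept, r_squared, r_squared_defined,
                                 n, model, x, y, p_value = NA_real_,
                                 matches = NULL) {
  coefs <- if (identical(model, "zero_intercept")) c(slope = slope)
           else c(intercept = intercept, slope = slope)
  structure(list(coefficients = coefs, slope = slope, intercept = intercept,
                 r_squared = r_squared, r_squared_defined = r_squared_defined,
                 n = n, model = model, p_value = p_value,
                 data = data.frame(x = x, y = y), matches = matches),
            class = "calibration_fit")
}

#' Zero-intercept calibration regression
#'
#' Least squares through the origin: slope \eqn{= \sum x_i y_i / \sum x_i^2}.
#' Used to calibrate flowering-pixel counts against manual flower counts,
#' where a line through the origin is the physically sensible model (no
#' flowering pixels before flowering commences).
#'
#' The reported \eqn{R^2 = 1 - \sum(y - \hat y)^2 / \sum y^2} uses the
#' **uncorrected** total sum of squares, the standard no-intercept convention.
#' It is not comparable to the mean-centered \eqn{R^2} of an intercept model
#' and, on pathological data, can fall outside \[0, 1\]; such values are
#' reported as-is with `r_squared_defined = FALSE` rather than clipped.
#'
#' @param x predictor values (e.g. flowering-pixel counts), `sum(x^2) > 0`.
#' @param y response values (e.g. manual flower counts), same length,
#'   n >= 2.
#' @return An object of class `calibration_fit`.
#' @seealso [fit_with_intercept()], [calibrate_counts_by_date()]
#' @examples
#' fit_zero_intercept(c(1, 2, 3), c(2, 4, 6))  # slope 2, R^2 = 1
#' @export
fit_zero_intercept <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) .stop2("need >= 2 points, got ", n)
  sxx <- sum(x^2)
  if (sxx == 0) .stop2("sum(x^2) is zero: slope undefined")
  slope <- sum(x * y) / sxx
  sse <- sum((y - slope * x)^2)
  syy <- sum(y^2)
  if (syy == 0) {
    r2 <- NA_real_; defined <- FALSE
  } else {
    r2 <- 1 - sse / syy
    defined <- r2 >= 0 && r2 <= 1
  }
  # F-test of the one-parameter model against the null of slope 0
  p <- if (n > 1L && sse > 0)
    stats::pf((syy - sse) / (sse / (n - 1L)), 1L, n - 1L, lower.tail = FALSE)
  else if (sse == 0 && syy > 0) 0 else NA_real_
  .new_calibration_fit(slope, NULL, r2, defined, n, "zero_intercept", x, y, p)
}

#' Ordinary least-squares fit with intercept
#'
#' Standard simple linear regression (via [stats::lm()]) with the
#' mean-centered \eqn{R^2}; used for the yield layers, where yield has a
#' nonzero base level independent of flowering signal.
#'
#' @param x predictor values, not constant, n >= 3.
#' @param y response values, same length.
#' @return An object of class `calibration_fit` (with `p_value` from the
#'   model F-test).
#' @export
fit_with_intercept <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) .stop2("need >= 3 points, got ", n)
  if (length(unique(x)) < 2L) .stop2("constant predictor: slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # warns on numerically perfect fits
  r2 <- sm$r.squared
  p <- if (is.null(sm$fstatistic)) NA_real_
       else unname(stats::pf(sm$fstatistic[1L], sm$fstatistic[2L],
                             sm$fstatistic[3L], lower.tail = FALSE))
  if (all(abs(stats::residuals(fit)) < 1e-10)) p <- 0
  .new_calibration_fit(unname(stats::coef(fit)[2L]),
                       unname(stats::coef(fit)[1L]),
                       r2, is.finite(r2) && r2 >= 0 && r2 <= 1, n,
                       "with_intercept", x, y, p)
}

#' @export
print.calibration_fit <- function(x, digits = 4, ...) {
  eqn <- if (identical(x$model, "zero_intercept"))
    sprintf("y = %sx", format(x$slope, digits = digits))
  else
    sprintf("y = %sx %s %s", format(x$slope, digits = digits),
            if (x$intercept < 0) "-" else "+",
            format(abs(x$intercept), digits = digits))
  cat(sprintf("<calibration_fit> %s model (n = %d)\n  %s,  R^2 = %s%s\n",
              x$model, x$n, eqn,
              if (is.na(x$r_squared)) "undefined"
              else format(x$r_squared, digits = digits),
              if (x$r_squared_defined || is.na(x$r_squared)) ""
              else " (outside [0,1]; flagged undefined)"))
  invisible(x)
}

#' @export
summary.calibration_fit <- function(object, ...) {
  print(object, ...)
  cat(sprintf("  F-test p = %s, significance: %s\n",
              format(object$p_value, digits = 3),
              .sig_class(object$p_value)))
  invisible(object)
}

#' @export
coef.calibration_fit <- function(object, ...) object$coefficients

#' @export
predict.calibration_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata$x else newdata
  (object$intercept %||% 0) + object$slope * x
}

#' @export
fitted.calibration_fit <- function(object, ...) predict(object)

#' @export
residuals.calibration_fit <- function(object, ...) object$data$y - fitted(object)

#' @export
plot.calibration_fit <- function(x, xlab = "x", ylab = "y", main = NULL, ...) {
  graphics::plot(x$data$x, x$data$y, xlab = xlab, ylab = ylab,
                 main = main %||% sprintf("%s fit, R^2 = %.2f", x$model,
                                          x$r_squared), ...)
  graphics::abline(a = x$intercept %||% 0, b = x$slope, col = "red3")
  invisible(x)
}

# Match each plot's pixel count at `date` with the manual count at the
# nearest reference date within `tolerance` days.  Returns a data frame of
# matched pairs; unmatched plots are reported via message().
.match_counts <- function(series, ref, date, tolerance) {
  mc <- ref$manual_counts
  if (is.null(mc)) .stop2("ground reference carries no manual counts")
  rows <- list()
  for (s in series) {
    i <- match(date, s$t)
    if (is.na(i)) next
    cand <- mc[mc$plot_id == s$plot_id, , drop = FALSE]
    if (!nrow(cand)) { message("no manual counts for plot ", s$plot_id); next }
    dd <- abs(cand$date_julian - date)
    j <- which.min(dd)
    if (dd[j] > tolerance) {
      message("plot ", s$plot_id, ": nearest manual count is ", dd[j],
              " days from day ", date, " (> tolerance ", tolerance, "); dropped")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      plot_id = s$plot_id, pixel_count = s$count[i],
      manual_count = cand$manual_count[j], image_date = date,
      manual_date = cand$date_julian[j])
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(plot_id = character(), pixel_count = numeric(),
                  manual_count = numeric(), image_date = numeric(),
                  manual_date = numeric())
}

#' Calibrate pixel counts against manual flower counts for one image date
#'
#' Zero-intercept regression of manual flower counts (response) on
#' flowering-pixel counts (predictor) across plots, for a single image date.
#' Manual counts are matched to the image date by nearest reference date
#' within `tolerance` days (field counts and flights are rarely same-day);
#' unmatched plots are dropped with a message.
#'
#' @param series list of [flowering_series()] (pixel counts per plot).
#' @param ref a [ground_reference()] with manual counts.
#' @param date Julian image date to calibrate.
#' @param tolerance maximum date mismatch in days (default 4).
#' @return A `calibration_fit` whose `matches` field records the matched
#'   (plot, pixel count, manual count, dates) pairs.
#' @export
calibrate_counts_by_date <- function(series, ref, date, tolerance = 4) {
  stopifnot(inherits(ref, "ground_reference"))
  m <- .match_counts(series, ref, date, tolerance)
  if (nrow(m) < 2L)
    .stop2("only ", nrow(m), " plot(s) matched at day ", date,
           "; need >= 2")
  fit <- fit_zero_intercept(m$pixel_count, m$manual_count)
  fit$matches <- m
  fit$date <- date
  fit
}

#' Screen single image dates against seed yield
#'
#' For each acquisition date, fits an intercept regression of yield on that
#' date's flowering-pixel counts across plots — the single-date screening
#' that motivates integrating over time instead.  Dates where the fit is not
#' estimable (fewer than 3 matched plots, or constant counts) get `NA`
#' statistics.
#'
#' @param series list of [flowering_series()].
#' @param ref a [ground_reference()] with a yield table.
#' @return Data frame with one row per date: `date_julian`, `n`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `sig_class` (`***`/`**`/`*`/`ns`
#'   from the model F-test at 0.001/0.01/0.05).
#' @export
screen_dates_vs_yield <- function(series, ref) {
  stopifnot(inherits(ref, "ground_reference"))
  if (is.null(ref$yield)) .stop2("ground reference carries no yield table")
  dates <- sort(unique(unlist(lapply(series, `[[`, "t"))))
  rows <- lapply(dates, function(d) {
    x <- numeric(); y <- numeric()
    for (s in series) {
      i <- match(d, s$t)
      j <- match(s$plot_id, ref$yield$plot_id)
      if (!is.na(i) && !is.na(j)) {
        x <- c(x, s$count[i]); y <- c(y, ref$yield$yield[j])
      }
    }
    fit <- tryCatch(fit_with_intercept(x, y), error = function(e) NULL)
    if (is.null(fit))
      data.frame(date_julian = d, n = length(x), slope = NA_real_,
                 intercept = NA_real_, r_squared = NA_real_,
                 p_value = NA_real_, sig_class = NA_character_)
    else
      data.frame(date_julian = d, n = fit$n, slope = fit$slope,
                 intercept = fit$intercept, r_squared = fit$r_squared,
                 p_value = fit$p_value, sig_class = .sig_class(fit$p_value))
  })
  do.call(rbind, rows)
}

#' Regress seed yield on integrated flowering (AUFPC)
#'
#' The season-level yield model: ordinary least squares of per-plot seed
#' yield on per-plot AUFPC, reported with slope, intercept and centered
#' \eqn{R^2}.
#'
#' @param aufpc a [compute_aufpc_batch()] result, list of `aufpc_result`, or
#'   an [aufpc_table()] data frame.
#' @param ref a [ground_reference()] with a yield table.
#' @return A `calibration_fit` (model `with_intercept`); its `matches` field
#'   records the matched plots.
#' @export
yield_vs_aufpc <- function(aufpc, ref) {
  stopifnot(inherits(ref, "ground_reference"))
  if (is.null(ref$yield)) .stop2("ground reference carries no yield table")
  tab <- if (is.data.frame(aufpc)) aufpc else aufpc_table(aufpc)
  j <- match(tab$plot_id, ref$yield$plot_id)
  keep <- !is.na(j)
  if (sum(keep) < 3L)
    .stop2("only ", sum(keep), " plot(s) with both AUFPC and yield; need >= 3")
  fit <- fit_with_intercept(tab$aufpc[keep], ref$yield$yield[j[keep]])
  fit$matches <- data.frame(plot_id = tab$plot_id[keep],
                            aufpc = tab$aufpc[keep],
                            yield = ref$yield$yield[j[keep]])
  fit
}
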