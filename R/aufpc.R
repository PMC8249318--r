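#' Area under the flowering progress curve (AUFPC)
#'
#' Integrates a plot's flowering-pixel counts over the season with a
#' first-observation baseline:
#' \deqn{AUFPC = \sum_{i=1}^{n-1} \left(\frac{F_i + F_{i+1}}{2} - F_1\right)
#'   (t_{i+1} - t_i)}
#' i.e. the trapezoid integral of \eqn{F} over \eqn{t} minus
#' \eqn{F_1 (t_n - t_1)}.  The baseline adjusts for lines that already show
#' flowering pixels at the first flight, so lines are compared on progress
#' beyond their own starting level (the AUDPC statistic of plant pathology,
#' baseline-adjusted).  The result can be negative if counts fall below the
#' first-date level; that is the statistic's behavior, not an error.  Units
#' are pixel-days.
#'
#' @param series a [flowering_series()] with at least 2 observations.
#' @return An object of class `aufpc_result`: list with `plot_id`, `aufpc`,
#'   `n_obs`, `t_span` (first and last date).
#' @examples
#' compute_aufpc(flowering_series("P1", t = c(0, 10), count = c(0, 10)))$aufpc  # 50
#' @export
compute_aufpc <- function(series) {
  stopifnot(inherits(series, "flowering_series"))
  n <- length(series$t)
  if (n < 2L)
    .stop2("AUFPC needs >= 2 observations; plot ", series$plot_id, " has ", n)
  t <- series$t; f <- series$count
  a <- sum(((f[-n] + f[-1L]) / 2 - f[1L]) * diff(t))
  structure(list(plot_id = series$plot_id, aufpc = a, n_obs = n,
                 t_span = c(t[1L], t[n])),
            class = "aufpc_result")
}

#' @export
print.aufpc_result <- function(x, ...) {
  cat(sprintf("<aufpc_result> %s: AUFPC %.6g pixel-days (%d obs, days %s-%s)\n",
              x$plot_id, x$aufpc, x$n_obs, format(x$t_span[1L]),
              format(x$t_span[2L])))
  invisible(x)
}

#' Batch AUFPC over many plots
#'
#' Applies [compute_aufpc()] to each series, collecting per-plot failures
#' (e.g. single-observation series) instead of aborting the batch.
#'
#' @param series list of [flowering_series()].
#' @return A list with `results` (list of `aufpc_result`, input order
#'   preserved for the valid series) and `errors` (data frame of `plot_id`,
#'   `message` for the failures).
#' @export
compute_aufpc_batch <- function(series) {
  results <- list(); errs <- list()
  for (s in series) {
    r <- tryCatch(compute_aufpc(s), error = function(e) e)
    if (inherits(r, "error"))
      errs[[length(errs) + 1L]] <- data.frame(plot_id = s$plot_id,
                                              message = conditionMessage(r))
    else results[[length(results) + 1L]] <- r
  }
  list(results = results,
       errors = if (length(errs)) do.call(rbind, errs)
                else data.frame(plot_id = character(), message = character()))
}

#' Tabulate batch AUFPC results
#'
#' @param batch result of [compute_aufpc_batch()] (or a list of
#'   `aufpc_result`).
#' @return Data frame with columns `plot_id`, `aufpc`, `n_obs`, `t_first`,
#'   `t_last`.
#' @export
aufpc_table <- function(batch) {
  results <- if (is.list(batch) && !is.null(batch$results)) batch$results else batch
  if (!length(results))
    return(data.frame(plot_id = character(), aufpc = numeric(),
                      n_obs = integer(), t_first = numeric(),
                      t_last = numeric()))
  do.call(rbind, lapply(results, function(r)
    data.frame(plot_id = r$plot_id, aufpc = r$aufpc, n_obs = r$n_obs,
               t_first = r$t_span[1L], t_last = r$t_span[2L])))
}
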