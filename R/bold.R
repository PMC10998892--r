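#' Construct a BOLD time series
#'
#' A regularly sampled signal together with its repetition time (TR).
#' All spectral operations in the package act on this class.
#'
#' @param values Numeric vector of signal values (arbitrary units), length
#'   at least 2, no missing values.
#' @param tr_seconds Repetition time in seconds (sampling interval), > 0.
#'   The study cohorts this package targets mix two dialects, 2.1 s and
#'   2.4 s; [harmonize_pair()] reconciles them before any comparison.
#' @param region_id Optional region label carried through to outputs.
#'
#' @return An object of class `bold_series` with elements `values`,
#'   `tr_seconds` and `region_id`.
#' @seealso [compute_power_spectrum()], [harmonize_pair()]
#' @export
bold_series <- function(values, tr_seconds, region_id = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop_config("a BOLD series needs at least 2 samples, got %d", length(values))
  }
  if (anyNA(values)) stop_data("BOLD series contains missing values")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stop_config("tr_seconds must be a single positive number")
  }
  structure(list(values = values, tr_seconds = as.numeric(tr_seconds),
                 region_id = region_id),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %d volumes @ TR %.3g s (%.1f s)%s\n",
              length(x$values), x$tr_seconds,
              length(x$values) * x$tr_seconds,
              if (is.null(x$region_id)) "" else paste0(" [", x$region_id, "]")))
  invisible(x)
}

#' @export
length.bold_series <- function(x) length(x$values)

duration_seconds <- function(series) length(series$values) * series$tr_seconds

#' Sample autocorrelation function of a BOLD series
#'
#' Computed on the demeaned series and normalized so that the lag-0 value
#' is exactly 1. The lag-k estimator divides the lagged cross-products by
#' the number of overlapping pairs (n - k), so an on-grid periodic signal
#' returns to 1 at its period.
#'
#' @param series A [bold_series()].
#' @param max_lag Maximum lag (in samples), strictly less than the series
#'   length.
#' @return Numeric vector of length `max_lag + 1` (lags 0..max_lag).
#' @export
autocorrelation <- function(series, max_lag) {
  stopifnot(inherits(series, "bold_series"))
  x <- series$values
  n <- length(x)
  if (max_lag >= n) stop_config("max_lag (%d) must be < series length (%d)", max_lag, n)
  x <- x - mean(x)
  v <- sum(x^2) / n
  if (v <= .Machine$double.eps) stop_data("zero-variance series: ACF undefined")
  vapply(0:max_lag, function(k) {
    (sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / (n - k)) / v
  }, numeric(1))
}
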