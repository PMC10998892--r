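#' One-sided power spectrum of a BOLD series
#'
#' Real-input discrete Fourier transform of the series; the squared
#' modulus of each retained component is reported at its frequency in Hz.
#' Total power is the plain sum of the retained squared amplitudes. The
#' DC component is excluded by default because the source signals are
#' demeaned / nuisance-regressed; a constant series then carries zero
#' power and is flagged as degenerate so that percentage-based operations
#' downstream can refuse it.
#'
#' @param series A [bold_series()].
#' @param exclude_dc Drop the zero-frequency component (default `TRUE`).
#' @return A `power_spectrum` object: `frequencies` (Hz, ascending),
#'   `squared_amplitudes`, `total_power`, `nyquist`, `dc_excluded`,
#'   `degenerate`.
#' @export
compute_power_spectrum <- function(series, exclude_dc = TRUE) {
  stopifnot(inherits(series, "bold_series"))
  x <- series$values
  n <- length(x)
  ft <- stats::fft(x)
  keep <- seq_len(floor(n / 2) + 1L)      # one-sided: k = 0 .. floor(n/2)
  sq <- Mod(ft[keep])^2
  freqs <- (keep - 1L) / (n * series$tr_seconds)
  if (exclude_dc) {
    sq <- sq[-1L]
    freqs <- freqs[-1L]
  }
  total <- sum(sq)
  structure(list(frequencies = freqs,
                 squared_amplitudes = sq,
                 total_power = total,
                 nyquist = 1 / (2 * series$tr_seconds),
                 dc_excluded = exclude_dc,
                 degenerate = total <= n * .Machine$double.eps * max(1, sum(abs(x)))),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d components up to %.4g Hz, total power %.4g%s\n",
              length(x$frequencies), x$nyquist, x$total_power,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

check_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (isTRUE(spectrum$degenerate) || spectrum$total_power <= 0) {
    stop_data("degenerate spectrum (zero total power): percentages undefined")
  }
}

#' Binned power distribution
#'
#' Tiles `[0, Nyquist]` with fixed-width frequency bins and reports the
#' percentage of total power in each bin. The bin width is chosen per
#' input by bisection so that the first occupied bin carries
#' approximately `target_first_bin_pct` of the total power; qualitative
#' results are insensitive to the exact width, so the approximation is
#' accepted at the bisection tolerance. An alternative `"equal_power"`
#' mode builds variable-width bins each holding the target fraction of
#' power.
#'
#' @param spectrum A non-degenerate `power_spectrum`.
#' @param target_first_bin_pct Desired percentage of total power in the
#'   first occupied bin (default 10).
#' @param method `"fixed"` (default; fixed-width bins, width tuned by
#'   bisection) or `"equal_power"` (variable-width bins of equal power).
#' @param delta_omega Optional explicit bin width in Hz; overrides the
#'   bisection.
#' @return A `binned_power` object: `bin_edges`, `percentages`,
#'   `delta_omega` (NA for the equal-power mode).
#' @export
binned_power_distribution <- function(spectrum, target_first_bin_pct = 10,
                                      method = c("fixed", "equal_power"),
                                      delta_omega = NULL) {
  check_spectrum(spectrum)
  method <- match.arg(method)
  f <- spectrum$frequencies
  p <- spectrum$squared_amplitudes
  total <- spectrum$total_power
  nyq <- spectrum$nyquist

  if (method == "equal_power") {
    ord <- order(f)
    cum <- pmin(cumsum(p[ord]) / total * 100, 100)
    cuts <- seq(target_first_bin_pct, 100, by = target_first_bin_pct)
    if (cuts[length(cuts)] < 100) cuts <- c(cuts, 100)
    idx <- findInterval(cum, cuts, left.open = TRUE)  # bin index per component
    pct <- vapply(seq_along(cuts), function(b) {
      sum(p[ord][idx == b - 1L]) / total * 100
    }, numeric(1))
    edges <- c(0, vapply(seq_along(cuts), function(b) {
      inb <- f[ord][idx == b - 1L]
      if (length(inb)) max(inb) else NA_real_
    }, numeric(1)))
    edges <- edges[!is.na(edges)]
    return(structure(list(bin_edges = edges, percentages = pct,
                          delta_omega = NA_real_),
                     class = "binned_power"))
  }

  bin_fixed <- function(dw) {
    idx <- pmax(1L, ceiling(f / dw - 1e-12))
    nb <- ceiling(nyq / dw - 1e-12)
    pct <- vapply(seq_len(nb), function(b) sum(p[idx == b]) / total * 100,
                  numeric(1))
    list(edges = seq(0, by = dw, length.out = nb + 1L), pct = pct)
  }
  first_occupied_pct <- function(dw) {
    b <- bin_fixed(dw)
    occ <- which(b$pct > 0)
    b$pct[occ[1L]]
  }

  if (is.null(delta_omega)) {
    lo <- min(f[p > 0]) / 4
    hi <- nyq
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (first_occupied_pct(mid) < target_first_bin_pct) lo <- mid else hi <- mid
    }
    delta_omega <- hi
  }
  b <- bin_fixed(delta_omega)
  structure(list(bin_edges = b$edges, percentages = b$pct,
                 delta_omega = delta_omega),
            class = "binned_power")
}

#' Cumulative power distribution
#'
#' Percentage of total spectral power accumulated up to each frequency
#' threshold. `"full"` resolution (one threshold per retained frequency,
#' prefixed with 0 Hz at 0%) is the substrate of the [das()] integral;
#' `"deciles"` places thresholds at 10%, 20%, ..., 100% of the Nyquist
#' frequency and is intended for reporting. The percent-threshold
#' convention is relative to Nyquist; the reference quantity is a
#' configurable choice, not forced by the definition.
#'
#' @param spectrum A non-degenerate `power_spectrum`.
#' @param thresholds `"full"` (default), `"deciles"`, or an ascending
#'   numeric vector of frequency thresholds in Hz.
#' @return A `cumulative_power` object: `thresholds` (Hz) and
#'   `cumulative_pct` (non-decreasing, ending at 100 when the last
#'   threshold reaches Nyquist).
#' @export
cumulative_power <- function(spectrum, thresholds = "full") {
  check_spectrum(spectrum)
  f <- spectrum$frequencies
  p <- spectrum$squared_amplitudes
  if (is.character(thresholds)) {
    thresholds <- match.arg(thresholds, c("full", "deciles"))
    thr <- switch(thresholds,
                  full = c(0, sort(unique(f))),
                  deciles = seq(0.1, 1, by = 0.1) * spectrum$nyquist)
  } else {
    thr <- as.numeric(thresholds)
    if (is.unsorted(thr, strictly = FALSE)) {
      stop_config("thresholds must be ascending")
    }
  }
  cp <- vapply(thr, function(t) sum(p[f <= t + 1e-12]), numeric(1)) /
    spectrum$total_power * 100
  structure(list(thresholds = thr, cumulative_pct = cp),
            class = "cumulative_power")
}

#' Harmonize two BOLD series for spectral comparison
#'
#' Two spectra are only comparable on a shared frequency comb, which
#' requires equal time durations. With equal TRs the shorter series is
#' zero-padded to the longer one's length. With different TRs (the 2.1 s
#' vs 2.4 s dialects) each series is zero-padded or truncated to the
#' common target duration (the longer of the two), leaving the residual
#' duration mismatch below one sample of the coarser TR;
#' cumulative-power curves are then interpolated onto a union frequency
#' grid inside [das()].
#'
#' @param a,b [bold_series()] objects.
#' @return A list with elements `a` and `b`, the harmonized series, plus
#'   `common_grid` (`TRUE` when the two frequency combs coincide).
#' @export
harmonize_pair <- function(a, b) {
  stopifnot(inherits(a, "bold_series"), inherits(b, "bold_series"))
  resize <- function(s, n_target) {
    n <- length(s$values)
    v <- if (n >= n_target) s$values[seq_len(n_target)]
         else c(s$values, rep(0, n_target - n))
    bold_series(v, s$tr_seconds, s$region_id)
  }
  if (isTRUE(all.equal(a$tr_seconds, b$tr_seconds))) {
    n <- max(length(a$values), length(b$values))
    return(list(a = resize(a, n), b = resize(b, n), common_grid = TRUE))
  }
  target <- max(duration_seconds(a), duration_seconds(b))
  na <- max(2L, as.integer(round(target / a$tr_seconds)))
  nb <- max(2L, as.integer(round(target / b$tr_seconds)))
  list(a = resize(a, na), b = resize(b, nb), common_grid = FALSE)
}

#' Dynamics Alteration Score between two cumulative power curves
#'
#' Signed area between two cumulative power distributions, integrated
#' over frequency by the trapezoidal rule. A positive score means the
#' first signal accumulates its power at lower frequencies, i.e. has
#' slower dynamics. The score is antisymmetric by construction. When the
#' two curves live on different frequency grids they are linearly
#' interpolated onto the union grid restricted to the common range
#' (cumulative power is monotone and bounded, so interpolation is safe).
#' By default the raw area (% x Hz) is divided by the frequency range so
#' scores are comparable across TR dialects.
#'
#' @param cp_i,cp_j `cumulative_power` objects (full resolution
#'   recommended).
#' @param normalize Divide the area by the frequency range (default
#'   `TRUE`).
#' @return A `das_score` object with `value`, `raw_area` and `range_hz`.
#' @export
das <- function(cp_i, cp_j, normalize = TRUE) {
  stopifnot(inherits(cp_i, "cumulative_power"), inherits(cp_j, "cumulative_power"))
  lo <- max(min(cp_i$thresholds), min(cp_j$thresholds))
  hi <- min(max(cp_i$thresholds), max(cp_j$thresholds))
  if (hi <= lo) stop_data("cumulative power grids do not overlap: DAS undefined")
  grid <- sort(unique(c(cp_i$thresholds, cp_j$thresholds)))
  grid <- grid[grid >= lo & grid <= hi]
  yi <- stats::approx(cp_i$thresholds, cp_i$cumulative_pct, xout = grid,
                      rule = 2, ties = "ordered")$y
  yj <- stats::approx(cp_j$thresholds, cp_j$cumulative_pct, xout = grid,
                      rule = 2, ties = "ordered")$y
  raw <- pracma::trapz(grid, yi - yj)
  value <- if (normalize) raw / (hi - lo) else raw
  structure(list(value = value, raw_area = raw, range_hz = c(lo, hi)),
            class = "das_score")
}

#' @export
print.das_score <- function(x, ...) {
  cat(sprintf("<das_score> %.6g (raw area %.6g %%*Hz over [%.4g, %.4g] Hz)\n",
              x$value, x$raw_area, x$range_hz[1], x$range_hz[2]))
  invisible(x)
}

#' DAS of a series against a reference series
#'
#' Convenience wrapper: harmonizes the pair, computes both full-resolution
#' cumulative power curves and returns the signed score of `series`
#' relative to `reference`.
#'
#' @param series,reference [bold_series()] objects.
#' @param normalize Passed to [das()].
#' @return A `das_score`.
#' @export
das_between_series <- function(series, reference, normalize = TRUE) {
  h <- harmonize_pair(series, reference)
  cpi <- cumulative_power(compute_power_spectrum(h$a), "full")
  cpj <- cumulative_power(compute_power_spectrum(h$b), "full")
  das(cpi, cpj, normalize = normalize)
}

#' Aggregate per-region DAS values
#'
#' Averaging signed scores and averaging magnitudes answer different
#' questions and are not interchangeable: the absolute value must be
#' taken per region *before* averaging to measure the magnitude of
#' alteration.
#'
#' @param per_region Numeric vector of per-region scores (length >= 1).
#' @param absolute Take `abs()` per region before averaging.
#' @return List with `mean` and `sem` (sample sd / sqrt(n); `NA` for a
#'   single region).
#' @export
aggregate_das <- function(per_region, absolute = FALSE) {
  per_region <- as.numeric(per_region)
  if (length(per_region) == 0L) stop_config("no region scores to aggregate")
  if (absolute) per_region <- abs(per_region)
  list(mean = mean(per_region),
       sem = if (length(per_region) > 1L)
         stats::sd(per_region) / sqrt(length(per_region)) else NA_real_)
}
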