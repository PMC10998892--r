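# Independent oracles and small fixture builders used across the suite.

# brute-force O(N^2) discrete Fourier transform, one-sided squared
# amplitudes; independent of stats::fft
naive_dft_power <- function(x, tr) {
  n <- length(x)
  ks <- 0:(n %/% 2)
  sq <- vapply(ks, function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    re^2 + im^2
  }, numeric(1))
  list(frequencies = ks / (n * tr), squared = sq)
}

# a valid random cumulative-power curve on a given frequency grid
random_cp <- function(grid, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(length(grid) - 1)
  cp <- c(0, cumsum(p) / sum(p) * 100)
  structure(list(thresholds = grid, cumulative_pct = cp),
            class = "cumulative_power")
}

# wrap a correlation matrix as a functional network without recomputing
as_fc <- function(m, ids = NULL) {
  ids <- ids %||% sprintf("r%02d", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  structure(list(matrix = m, region_ids = ids), class = "functional_network")
}

# random valid correlation matrix via random BOLD-like data
random_fc <- function(n_regions, n_time = 60, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n_time * n_regions), n_time, n_regions)
  as_fc(stats::cor(X))
}

# random symmetric non-negative connectome
random_connectome <- function(n = 12, density = 0.5, seed = 1,
                              log_scale = FALSE) {
  set.seed(seed)
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  vals <- stats::rlnorm(sum(ut), 3, 1) * (stats::runif(sum(ut)) < density)
  m[ut] <- vals
  m <- m + t(m)
  connectome(m, log_scale = log_scale)
}

# small, fast cohort configuration for predictor unit tests; any
# sim_config() argument can be overridden
small_sim <- function(...) {
  args <- utils::modifyList(
    list(n_controls = 4L, n_patients = 4L, n_atlas_labels = 24L,
         n_empty_labels = 2L, n_regions_dmn = 4L, region_voxels = 27L,
         grid_dim = c(30L, 30L, 20L), backbone_density = 0.3,
         tumor_volume_voxels = 60L),
    list(...))
  do.call(sim_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
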