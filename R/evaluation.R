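#' Reconstruction metrics between flattened graphs
#'
#' Mean squared error, mean absolute error, Pearson correlation and
#' cosine similarity between a predicted and a ground-truth edge vector
#' (raw, unfiltered, log-scale vectors by convention).
#'
#' @param pred,truth Numeric vectors of equal length >= 2.
#' @return List with `mse`, `mae`, `pcc`, `cs`. `pcc` is `NA` with a
#'   warning when the truth has zero variance.
#' @export
reconstruction_metrics <- function(pred, truth) {
  pred <- as.numeric(pred); truth <- as.numeric(truth)
  if (length(pred) != length(truth) || length(pred) < 2L) {
    stop_config("pred and truth must have equal length >= 2")
  }
  pcc <- if (stats::sd(truth) == 0 || stats::sd(pred) == 0) {
    warning("zero-variance vector: PCC undefined")
    NA_real_
  } else {
    stats::cor(pred, truth)
  }
  np <- sqrt(sum(pred^2)); nt <- sqrt(sum(truth^2))
  cs <- if (np == 0 || nt == 0) 0 else sum(pred * truth) / (np * nt)
  list(mse = mean((pred - truth)^2),
       mae = mean(abs(pred - truth)),
       pcc = pcc, cs = cs)
}

#' Weight probability distribution of a connectome
#'
#' Histogram of the positive log-scale edge weights, used in place of
#' the more common degree distribution because the graphs are weighted.
#' Empty bins are epsilon-smoothed and the histogram renormalized so
#' that divergences are finite.
#'
#' @param c A `connectome` in log scale (or a numeric vector of positive
#'   log-weights).
#' @param n_bins Number of bins (default 50).
#' @param range Numeric length-2 binning range; compute it from the
#'   pooled pair being compared so two distributions share a binning
#'   (see [weight_distribution_pair()]).
#' @param epsilon Smoothing mass added to every bin before
#'   renormalization (default 1e-10).
#' @return A `weight_distribution`: `bin_edges`, `probabilities`,
#'   `epsilon`.
#' @export
weight_distribution <- function(c, n_bins = 50, range = NULL, epsilon = 1e-10) {
  w <- if (inherits(c, "connectome")) {
    if (!c$log_scale) stop_data("weight distributions are computed on the log scale")
    c$weights[upper.tri(c$weights)]
  } else {
    as.numeric(c)
  }
  w <- w[w > 0]
  if (length(w) == 0L && is.null(range)) {
    stop_data("no positive edges: weight distribution undefined")
  }
  if (is.null(range)) range <- base::range(w)
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  if (length(w) == 0L) {
    # an empty graph on a shared binning is pure smoothing mass:
    # maximally distant from any occupied histogram
    counts <- rep(0, n_bins)
    p <- rep(1 / n_bins, n_bins)
  } else {
    idx <- pmin(pmax(findInterval(w, edges, rightmost.closed = TRUE,
                                  left.open = TRUE), 1L), n_bins)
    counts <- tabulate(idx, nbins = n_bins)
    p <- counts / sum(counts) + epsilon
  }
  structure(list(bin_edges = edges, probabilities = p / sum(p),
                 epsilon = epsilon),
            class = "weight_distribution")
}

#' Weight distributions of two connectomes on a shared binning
#'
#' @param a,b `connectome` objects in log scale (or numeric log-weight
#'   vectors).
#' @inheritParams weight_distribution
#' @return List with `p` and `q`, two `weight_distribution` objects on
#'   identical bin edges.
#' @export
weight_distribution_pair <- function(a, b, n_bins = 50, epsilon = 1e-10) {
  pos <- function(x) {
    w <- if (inherits(x, "connectome")) x$weights[upper.tri(x$weights)] else as.numeric(x)
    w[w > 0]
  }
  pooled <- c(pos(a), pos(b))
  if (length(pooled) == 0L) stop_data("no positive edges in either connectome")
  rng <- base::range(pooled)
  list(p = weight_distribution(a, n_bins, rng, epsilon),
       q = weight_distribution(b, n_bins, rng, epsilon))
}

check_same_binning <- function(p, q) {
  stopifnot(inherits(p, "weight_distribution"), inherits(q, "weight_distribution"))
  if (length(p$bin_edges) != length(q$bin_edges) ||
      max(abs(p$bin_edges - q$bin_edges)) > 1e-12) {
    stop_data("distributions use different binnings; rebuild with a shared range")
  }
}

#' Kullback-Leibler divergence (base-2) between weight distributions
#'
#' sum p * log2(p / q) on epsilon-smoothed histograms with identical
#' binning. Base-2 logarithms are used throughout so the companion
#' Jensen-Shannon divergence is bounded by 1.
#'
#' @param p,q `weight_distribution` objects on identical bin edges.
#' @return Non-negative scalar (bits).
#' @export
kl_divergence <- function(p, q) {
  check_same_binning(p, q)
  sum(p$probabilities * log2(p$probabilities / q$probabilities))
}

#' Jensen-Shannon divergence (base-2) between weight distributions
#'
#' 0.5 * KL(p || m) + 0.5 * KL(q || m) with m = (p + q) / 2. Symmetric
#' and bounded in \[0, 1\] with base-2 logarithms, so it is interpretable
#' as a distance between the two distributions.
#'
#' @inheritParams kl_divergence
#' @return Scalar in \[0, 1\].
#' @export
js_divergence <- function(p, q) {
  check_same_binning(p, q)
  m <- (p$probabilities + q$probabilities) / 2
  0.5 * sum(p$probabilities * log2(p$probabilities / m)) +
    0.5 * sum(q$probabilities * log2(q$probabilities / m))
}

#' Z-scores of per-fold metric values
#'
#' Standardizes a metric across cross-validation folds by subtracting
#' the mean and dividing by the sample (n - 1) standard deviation.
#'
#' @param metric_values Numeric vector, length >= 3, nonzero variance.
#' @return Numeric vector with mean 0 and sample sd 1.
#' @export
fold_zscores <- function(metric_values) {
  x <- as.numeric(metric_values)
  if (length(x) < 3L) stop_config("need at least 3 folds to standardize")
  s <- stats::sd(x)
  if (s == 0) stop_data("zero variance across folds: z-scores undefined")
  (x - mean(x)) / s
}

#' Grubbs single-outlier test
#'
#' Compares the maximum standardized deviation G = max |x - mean| / sd
#' with the Student-t-based critical value
#' G_crit = ((n - 1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2)), where t is the
#' upper alpha/(2n) (two-tailed) or alpha/n (one-tailed) quantile of the
#' t distribution with n - 2 degrees of freedom.
#'
#' @param values Numeric vector, length >= 3.
#' @param alpha Significance level (default 0.05).
#' @param two_tailed Two-tailed test (default `TRUE`).
#' @return List with `is_outlier`, `g_statistic`, `critical_value`,
#'   `index` (position of the most extreme value).
#' @export
grubbs_test <- function(values, alpha = 0.05, two_tailed = TRUE) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3L) stop_config("Grubbs test needs at least 3 values")
  s <- stats::sd(x)
  if (s == 0) {
    warning("zero variance: no outlier detectable")
    return(list(is_outlier = FALSE, g_statistic = 0,
                critical_value = NA_real_, index = NA_integer_))
  }
  dev <- abs(x - mean(x)) / s
  g <- max(dev)
  idx <- which.max(dev)
  tails <- if (two_tailed) 2 else 1
  t2 <- stats::qt(alpha / (tails * n), df = n - 2, lower.tail = FALSE)^2
  crit <- (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
  list(is_outlier = g > crit, g_statistic = g, critical_value = crit,
       index = idx)
}

#' Q-Q normality check via quantile correlation
#'
#' Pearson correlation between the sorted sample and standard-normal
#' quantiles at plotting positions (i - 0.5) / n, with the two-tailed p
#' value from the correlation test. High r (> 0.9) with small p supports
#' normality of the fold scores.
#'
#' @param zscores Numeric vector, length >= 5, not all tied.
#' @return List with `r` and `p`.
#' @export
qq_normality <- function(zscores) {
  x <- as.numeric(zscores)
  n <- length(x)
  if (n < 5L) stop_config("need at least 5 values for a Q-Q check")
  if (stats::sd(x) == 0) stop_data("all values tied: Q-Q correlation undefined")
  theo <- stats::qnorm((seq_len(n) - 0.5) / n)
  ct <- stats::cor.test(sort(x), theo, alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}
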