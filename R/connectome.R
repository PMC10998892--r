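#' Construct a weighted structural connectome
#'
#' A symmetric non-negative matrix over atlas nodes with an active-node
#' mask. The default atlas dialect has 170 labels of which 4 are empty
#' (inactive), leaving 166 active nodes. Weights are native streamline
#' counts until [log_transform()] is applied.
#'
#' @param weights Square numeric matrix, symmetric, zero diagonal,
#'   non-negative (in native scale).
#' @param node_labels Optional character vector of node labels.
#' @param active_mask Logical vector marking active nodes; inactive
#'   rows/columns must be all zero. Defaults to all active.
#' @param log_scale `TRUE` once weights are log(1 + w) transformed.
#' @return A `connectome` object.
#' @export
connectome <- function(weights, node_labels = NULL, active_mask = NULL,
                       log_scale = FALSE) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop_config("connectome matrix must be square")
  if (max(abs(weights - t(weights))) > 1e-10) {
    stop_data("connectome matrix is not symmetric (tolerance 1e-10)")
  }
  weights <- (weights + t(weights)) / 2
  if (any(abs(diag(weights)) > 1e-12)) stop_data("connectome diagonal must be zero")
  diag(weights) <- 0
  if (!log_scale && any(weights < 0)) stop_data("native weights must be non-negative")
  if (is.null(active_mask)) active_mask <- rep(TRUE, n)
  if (length(active_mask) != n) stop_config("active_mask length mismatch")
  if (any(weights[!active_mask, ] != 0) || any(weights[, !active_mask] != 0)) {
    stop_data("inactive node rows/columns must be all zero")
  }
  if (is.null(node_labels)) node_labels <- sprintf("node_%03d", seq_len(n))
  dimnames(weights) <- list(node_labels, node_labels)
  structure(list(weights = weights, node_labels = node_labels,
                 active_mask = as.logical(active_mask),
                 log_scale = isTRUE(log_scale)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d nodes (%d active), %d edges, %s scale\n",
              length(x$node_labels), sum(x$active_mask),
              sum(x$weights[upper.tri(x$weights)] > 0),
              if (x$log_scale) "log(1+w)" else "native"))
  invisible(x)
}

check_compatible <- function(a, b) {
  if (!identical(a$node_labels, b$node_labels) ||
      !identical(a$active_mask, b$active_mask)) {
    stop_data("connectomes have mismatched node labels or active masks")
  }
  if (!identical(a$log_scale, b$log_scale)) {
    stop_data("connectomes are on different weight scales")
  }
}

#' Count streamlines intersecting a lesion mask
#'
#' A streamline intersects the lesion when at least one of its vertices
#' falls in a lesion voxel. Vertices are mapped to voxels by
#' `floor()` of their coordinates (vertex-in-voxel; adequate at
#' sub-voxel integration step sizes, and documented as such).
#'
#' @param streamlines List of numeric matrices (vertices x 3), each a 3D
#'   polyline.
#' @param lesion Integer voxel-coordinate matrix (n x 3); may be empty,
#'   in which case 0 is returned with a warning.
#' @return Integer count of intersecting streamlines.
#' @export
intersect_streamlines <- function(streamlines, lesion) {
  if (length(streamlines) == 0L) stop_config("no streamlines supplied")
  if (NROW(lesion) == 0L) {
    warning("empty lesion mask: intersection count is 0")
    return(0L)
  }
  lk <- unique(voxel_key(lesion))
  sum(vapply(streamlines, function(s) {
    if (is.null(dim(s))) s <- matrix(s, ncol = 3)
    any(voxel_key(floor(s)) %in% lk)
  }, logical(1)))
}

#' Lesion streamline budget from a healthy cohort
#'
#' The number of streamlines to seed inside a lesion is the arithmetic
#' mean of the per-control counts of streamlines intersecting that
#' lesion, rounded half-up to an integer (a streamline count must be
#' integral).
#'
#' @param per_control_counts Non-negative integer vector, one count per
#'   control subject.
#' @return A `lesion_budget`: `n_streamlines` and `per_control_counts`.
#' @export
lesion_streamline_budget <- function(per_control_counts) {
  counts <- as.numeric(per_control_counts)
  if (length(counts) == 0L) stop_config("need at least one control count")
  if (any(counts < 0)) stop_data("streamline counts must be non-negative")
  structure(list(n_streamlines = as.integer(floor(mean(counts) + 0.5)),
                 per_control_counts = counts),
            class = "lesion_budget")
}

#' Greedy merge of healthy and lesion connectomes
#'
#' Elementwise maximum of the two connectivity strengths per region
#' pair: w_ij = max(w_ij_healthy, w_ij_lesion). Commutative, idempotent
#' and monotone; symmetry and the zero diagonal are preserved.
#'
#' @param healthy,lesion `connectome` objects on identical labels and
#'   the same weight scale.
#' @return The merged `connectome`.
#' @export
greedy_merge <- function(healthy, lesion) {
  stopifnot(inherits(healthy, "connectome"), inherits(lesion, "connectome"))
  check_compatible(healthy, lesion)
  connectome(pmax(healthy$weights, lesion$weights),
             healthy$node_labels, healthy$active_mask, healthy$log_scale)
}

#' Log-weight normalization and its inverse
#'
#' Native streamline weights reach ~10^3; to prevent numerical overflow
#' and enhance differences among weaker connections all weights are
#' mapped through log(1 + w) before entering the predictor. The inverse
#' is exp(x) - 1; the round trip is the identity to well below 1e-9.
#'
#' @param c A `connectome` in native scale (log scale for the inverse).
#' @return The transformed `connectome` with the scale flag flipped.
#' @export
log_transform <- function(c) {
  stopifnot(inherits(c, "connectome"))
  if (c$log_scale) stop_data("connectome already in log scale")
  connectome(log1p(c$weights), c$node_labels, c$active_mask, log_scale = TRUE)
}

#' @rdname log_transform
#' @export
inverse_log_transform <- function(c) {
  stopifnot(inherits(c, "connectome"))
  if (!c$log_scale) stop_data("connectome already in native scale")
  w <- expm1(c$weights)
  w[w < 0] <- 0  # guard tiny negative rounding
  connectome(w, c$node_labels, c$active_mask, log_scale = FALSE)
}

#' Weighted degree distribution
#'
#' Per-active-node sum of incident native weights. The sum of weighted
#' degrees equals twice the total upper-triangle weight (handshake
#' identity).
#'
#' @param c A `connectome` in native scale.
#' @return Named numeric vector over active nodes.
#' @export
weighted_degree_distribution <- function(c) {
  stopifnot(inherits(c, "connectome"))
  if (c$log_scale) stop_data("weighted degrees are defined on the native scale")
  rowSums(c$weights)[c$active_mask]
}

#' Maximum-likelihood power-law tail fit
#'
#' Fits the tail x >= xmin of a positive sample to a continuous power
#' law p(x) ~ x^(-alpha) using the maximum-likelihood exponent
#' alpha = 1 + n / sum(log(x_i / xmin)). When `xmin` is not supplied it
#' is chosen by minimizing the Kolmogorov-Smirnov distance D between the
#' empirical tail and the fitted distribution over candidate values of
#' the observed sample. The exponent's standard error is
#' (alpha - 1) / sqrt(n).
#'
#' @param values Positive numeric sample (>= 10 positive values).
#' @param xmin Optional fixed lower cutoff; skips the KS scan.
#' @param max_candidates Cap on the number of scanned xmin candidates
#'   (quantile-spaced; default 100).
#' @return A `powerlaw_fit`: `alpha`, `xmin`, `ks_distance`, `alpha_se`,
#'   `n_tail`.
#' @export
fit_powerlaw_tail <- function(values, xmin = NULL, max_candidates = 100L) {
  x <- as.numeric(values)
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 10L) stop_data("need at least 10 positive values for a tail fit")
  fit_at <- function(xm) {
    tail <- x[x >= xm]
    n <- length(tail)
    s <- sum(log(tail / xm))
    if (n < 2L || s <= 0) return(NULL)
    alpha <- 1 + n / s
    st <- sort(tail)
    emp <- seq_len(n) / n
    theo <- 1 - (st / xm)^(1 - alpha)
    list(alpha = alpha, xmin = xm,
         ks_distance = max(abs(emp - theo), abs(emp - 1 / n - theo)),
         alpha_se = (alpha - 1) / sqrt(n), n_tail = n)
  }
  if (!is.null(xmin)) {
    tail <- x[x >= xmin]
    n <- length(tail)
    if (n < 2L) stop_numeric("fewer than 2 tail points above xmin")
    s <- sum(log(tail / xmin))
    if (s <= 0) stop_numeric("degenerate tail: all values at xmin")
    f <- fit_at(xmin)
    return(structure(f, class = "powerlaw_fit"))
  }
  cand <- sort(unique(x))
  cand <- cand[cand < max(x)]  # need >= 2 tail points
  if (length(cand) > max_candidates) {
    cand <- unique(stats::quantile(cand, probs = seq(0, 0.95, length.out = max_candidates),
                                   type = 1, names = FALSE))
  }
  fits <- Filter(function(f) !is.null(f) && f$n_tail >= 10L, lapply(cand, fit_at))
  if (length(fits) == 0L) stop_numeric("power-law tail fit failed: no viable xmin")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "ks_distance"))]]
  structure(best, class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> alpha = %.3f (se %.3f), xmin = %.4g, D = %.3f, n_tail = %d\n",
              x$alpha, x$alpha_se, x$xmin, x$ks_distance, x$n_tail))
  invisible(x)
}
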