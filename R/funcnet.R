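#' Mean BOLD series inside a voxel mask
#'
#' Extracts the voxel-wise mean signal at each time point for the voxels
#' in a binary mask; the TR is inherited from the member series.
#'
#' @param voxel_series Named list mapping voxel keys (as produced by
#'   [voxel_key()]) to [bold_series()] objects.
#' @param mask Integer matrix of voxel coordinates (rows = voxels,
#'   columns = x, y, z).
#' @param region_id Optional label for the resulting series.
#' @return A [bold_series()].
#' @export
extract_mean_series <- function(voxel_series, mask, region_id = NULL) {
  keys <- voxel_key(mask)
  if (length(keys) == 0L) stop_data("empty mask: no series to extract")
  missing <- setdiff(keys, names(voxel_series))
  if (length(missing)) {
    stop_data("mask voxels not covered by voxel_series (e.g. %s)", missing[1])
  }
  mats <- vapply(voxel_series[keys], function(s) s$values,
                 numeric(length(voxel_series[[keys[1]]]$values)))
  bold_series(rowMeans(as.matrix(mats)),
              voxel_series[[keys[1]]]$tr_seconds, region_id)
}

#' Canonical string key for integer voxel coordinates
#'
#' @param coords Integer matrix (n x 3) or length-3 vector.
#' @return Character vector of `"x_y_z"` keys.
#' @export
voxel_key <- function(coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  apply(coords, 1L, paste, collapse = "_")
}

#' Pairwise-Pearson functional connectivity matrix
#'
#' @param series Named list of [bold_series()], one per region, equal
#'   lengths (harmonize first if TRs differ).
#' @return A `functional_network`: symmetric correlation `matrix` with
#'   unit diagonal and `region_ids`.
#' @export
build_fc_matrix <- function(series) {
  if (length(series) < 2L) stop_config("need at least 2 regions for a network")
  lens <- vapply(series, function(s) length(s$values), integer(1))
  if (length(unique(lens)) != 1L) {
    stop_data("region series have unequal lengths; harmonize first")
  }
  X <- vapply(series, function(s) s$values, numeric(lens[1]))
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop_data("zero-variance region(s): %s",
              paste(names(series)[sds == 0], collapse = ", "))
  }
  m <- stats::cor(X)
  ids <- names(series) %||% paste0("region_", seq_along(series))
  dimnames(m) <- list(ids, ids)
  structure(list(matrix = m, region_ids = ids), class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("<functional_network> %d regions, mean |r| = %.3f\n",
              length(x$region_ids),
              mean(abs(x$matrix[upper.tri(x$matrix)]))))
  invisible(x)
}

#' Theta richness of a functional network
#'
#' Network complexity scored by how far the histogram of pairwise
#' correlations departs from uniformity:
#' Theta = 1 - m / (2(m - 1)) * sum_mu |P_mu - 1/m|,
#' where P_mu is the m-bin histogram (fixed support \[-1, 1\], so scores
#' are comparable across subjects) of the upper-triangle correlations.
#' Theta is 1 for a perfectly uniform correlation distribution and 0 when
#' all correlations fall in a single bin. Sensible m ranges from 10 to
#' 20; the default follows the convention m = 15.
#'
#' @param net A `functional_network`, or a numeric vector of correlations.
#' @param m Number of histogram bins (>= 2).
#' @return A `richness_score`: `theta`, `m`, `histogram`.
#' @export
theta_richness <- function(net, m = 15) {
  if (m < 2) stop_config("m must be >= 2")
  r <- if (inherits(net, "functional_network")) {
    net$matrix[upper.tri(net$matrix)]
  } else {
    as.numeric(net)
  }
  if (length(r) < 2L) stop_config("need at least 2 off-diagonal correlations")
  edges <- seq(-1, 1, length.out = m + 1L)
  idx <- pmin(pmax(findInterval(r, edges, rightmost.closed = TRUE,
                                left.open = TRUE), 1L), m)
  hist <- tabulate(idx, nbins = m) / length(r)
  theta <- 1 - m / (2 * (m - 1)) * sum(abs(hist - 1 / m))
  structure(list(theta = theta, m = as.integer(m), histogram = hist),
            class = "richness_score")
}

#' @export
print.richness_score <- function(x, ...) {
  cat(sprintf("<richness_score> Theta = %.4f (m = %d)\n", x$theta, x$m))
  invisible(x)
}

#' Change in richness relative to a healthy reference
#'
#' @param patient,healthy_reference `richness_score` objects with the
#'   same number of bins.
#' @return Signed difference (patient minus reference).
#' @export
delta_theta <- function(patient, healthy_reference) {
  stopifnot(inherits(patient, "richness_score"),
            inherits(healthy_reference, "richness_score"))
  if (patient$m != healthy_reference$m) {
    stop_config("richness scores use different bin counts (%d vs %d)",
                patient$m, healthy_reference$m)
  }
  patient$theta - healthy_reference$theta
}

#' Node-wise similarity between a patient network and a healthy pool
#'
#' Each row of the patient adjacency matrix is treated as a vector and
#' correlated (Pearson) with the same row of every healthy network; the
#' diagonal entry is removed first, since a shared unit diagonal would
#' inflate the correlations. The mean and standard error are taken over
#' all (node, healthy subject) pairs.
#'
#' @param patient A `functional_network`.
#' @param healthy List of `functional_network` objects on the same
#'   regions in the same order.
#' @return List with `mean`, `sem` and the matrix of per-pair
#'   correlations (`nodes x healthy`).
#' @export
node_similarity <- function(patient, healthy) {
  stopifnot(inherits(patient, "functional_network"))
  if (inherits(healthy, "functional_network")) healthy <- list(healthy)
  for (h in healthy) {
    if (!identical(h$region_ids, patient$region_ids)) {
      stop_data("healthy network regions do not match the patient network")
    }
  }
  n <- length(patient$region_ids)
  sims <- vapply(healthy, function(h) {
    vapply(seq_len(n), function(r) {
      stats::cor(patient$matrix[r, -r], h$matrix[r, -r])
    }, numeric(1))
  }, numeric(n))
  sims <- as.matrix(sims)
  vals <- as.numeric(sims)
  list(mean = mean(vals),
       sem = if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals)) else NA_real_,
       per_pair = sims)
}

#' Entrywise mean of a pool of functional networks
#'
#' The healthy reference network used for richness comparisons.
#'
#' @param nets List of `functional_network` objects on identical regions.
#' @return A `functional_network`.
#' @export
mean_network <- function(nets) {
  stopifnot(length(nets) >= 1L)
  ids <- nets[[1]]$region_ids
  for (h in nets) {
    if (!identical(h$region_ids, ids)) stop_data("networks on mismatched regions")
  }
  m <- Reduce(`+`, lapply(nets, `[[`, "matrix")) / length(nets)
  structure(list(matrix = m, region_ids = ids), class = "functional_network")
}

#' Tumor / network spatial overlap
#'
#' Fraction of network-mask voxels covered by the tumor mask:
#' |Tumor intersect DMN| / |DMN|. An overlap of 1 means a tumor covering
#' the entire network.
#'
#' @param tumor,dmn Integer voxel-coordinate matrices (n x 3).
#' @return An `overlap_score`: `value`, `tumor_voxels_in_dmn`,
#'   `dmn_voxels`.
#' @export
tumor_dmn_overlap <- function(tumor, dmn) {
  dk <- unique(voxel_key(dmn))
  if (length(dk) == 0L) stop_config("empty network mask")
  tk <- if (is.null(tumor) || NROW(tumor) == 0L) character(0)
        else unique(voxel_key(tumor))
  inter <- length(intersect(tk, dk))
  structure(list(value = inter / length(dk),
                 tumor_voxels_in_dmn = inter,
                 dmn_voxels = length(dk)),
            class = "overlap_score")
}

#' Mean Euclidean distance from a tumor centroid to region centroids
#'
#' @param tumor Integer voxel matrix (n x 3), non-empty.
#' @param dmn_regions List of non-empty voxel matrices, one per region.
#' @return List with `mean`, `sem` and the per-region `distances`.
#' @export
centroid_distance <- function(tumor, dmn_regions) {
  if (NROW(tumor) == 0L) stop_config("empty tumor mask")
  if (is.null(dim(tumor))) tumor <- matrix(tumor, ncol = 3)
  tc <- colMeans(tumor)
  d <- vapply(dmn_regions, function(reg) {
    if (NROW(reg) == 0L) stop_config("empty region mask")
    if (is.null(dim(reg))) reg <- matrix(reg, ncol = 3)
    sqrt(sum((colMeans(reg) - tc)^2))
  }, numeric(1))
  list(mean = mean(d),
       sem = if (length(d) > 1L) stats::sd(d) / sqrt(length(d)) else NA_real_,
       distances = d)
}
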