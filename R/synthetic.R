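#' Simulation configuration for a synthetic surgical cohort
#'
#' Bundles every knob of the synthetic data generator. Defaults encode
#' the acquisition and cohort conditions the package targets: 183
#' volumes per BOLD run, two repetition-time dialects (2.1 s and 2.4 s)
#' assigned round-robin, 41 default-mode regions, a 170-label atlas with
#' 4 empty labels (166 active nodes), lognormal edge weights with native
#' scale around 10^3 streamlines, and a hop-based surgery operator.
#'
#' @param n_controls,n_patients Cohort sizes (defaults 10 and 20).
#' @param n_regions_dmn Number of default-mode regions (default 41).
#' @param n_volumes BOLD volumes per run (default 183, the acquisition
#'   time divided by the 2.1 s TR).
#' @param tr_options Repetition-time dialects in seconds, assigned
#'   round-robin across subjects (default `c(2.1, 2.4)`).
#' @param bold_noise_sd White-noise standard deviation added to the unit
#'   root-mean-square oscillatory mixture (default 0.1).
#' @param spectral_tilt Per-patient spectral tilt; positive shifts power
#'   toward low frequencies (slower dynamics). Default: evenly spaced on
#'   \[-2, 2\]. Controls are untilted.
#' @param tumor_volume_voxels Per-patient tumor volumes in voxels;
#'   default lognormal around a median of 480 voxels (about 13 cm^3 at
#'   3 mm voxels).
#' @param overlap_targets Per-patient target tumor/DMN overlap fraction
#'   (default uniform on \[0, 0.08\]).
#' @param lesion_labels Per-patient lobe labels recycled from
#'   `c("frontal", "temporal", "parietal")`.
#' @param periventricular_rate Probability that a tumor is flagged
#'   periventricular (default 0.25, mirroring roughly a quarter of a
#'   typical cohort). The flag is metadata: it drives grouping in
#'   reports, not the generative model.
#' @param n_atlas_labels,n_empty_labels Atlas dialect (defaults 170 and
#'   4; the empty labels are inactive nodes).
#' @param backbone_density Probability that an active node pair belongs
#'   to the shared healthy backbone (default 0.15).
#' @param lognormal_mu,lognormal_sigma Log-mean and log-sd of native
#'   edge weights (defaults `log(1000)` and 1).
#' @param edge_variance_fraction Fraction of the log-weight variance
#'   attributed to edge identity, shared across subjects (default
#'   0.88).
#' @param subject_global_fraction Fraction attributed to a per-subject
#'   global gain, common to every edge of a subject (default 0.10), as
#'   overall connectivity strength differences dominate inter-subject
#'   variability in real cohorts; the remainder is i.i.d. per-edge
#'   residual. Pooled log-weights are exactly N(mu, sigma^2) for any
#'   admissible split.
#' @param plasticity_sd Log-scale standard deviation of the per-edge
#'   normative post-surgery reorganization shift, drawn once per cohort
#'   and shared across patients (default 0.3; 0 disables it, leaving
#'   the surgery operator exactly multiplicative).
#' @param spurious_edge_rate Per-subject probability that a non-backbone
#'   pair carries a (spurious) connection (default 0.02), so that prior
#'   thresholding has something to remove.
#' @param tumor_attenuation Multiplier applied to lesion-territory
#'   edges in the pre-surgery matrix, in \[0, 1\] (default 0.7). The
#'   pre-surgery network of a tumor patient is itself a lesioned
#'   network, and this signature is what makes the surgery outcome
#'   predictable from the input.
#' @param surgery_attenuation Multiplier applied to surgery-affected
#'   edges of the pre-surgery matrix to obtain the post-surgery matrix,
#'   in \[0, 1\] (default 0.5; 1 leaves the matrix untouched, 0 removes
#'   the edges).
#' @param surgery_radius Graph-hop radius of the resection around
#'   lesion-adjacent nodes (default 1: edges incident to lesion nodes).
#' @param post_noise_sd Log-scale sd of multiplicative noise applied to
#'   all post-surgery edges (default 0.05, a mild scan-rescan level).
#' @param grid_dim Integer extent of the abstract voxel lattice
#'   (default `c(60, 60, 40)`); masks are plain coordinate sets with no
#'   affine or world geometry.
#' @param region_voxels Voxels per synthetic DMN region blob (default 64).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_controls = 10L, n_patients = 20L,
                       n_regions_dmn = 41L, n_volumes = 183L,
                       tr_options = c(2.1, 2.4), bold_noise_sd = 0.1,
                       spectral_tilt = NULL, tumor_volume_voxels = NULL,
                       overlap_targets = NULL,
                       lesion_labels = NULL, periventricular_rate = 0.25,
                       n_atlas_labels = 170L, n_empty_labels = 4L,
                       backbone_density = 0.15,
                       lognormal_mu = log(1000), lognormal_sigma = 1,
                       edge_variance_fraction = 0.88,
                       subject_global_fraction = 0.10,
                       plasticity_sd = 0.3,
                       spurious_edge_rate = 0.02,
                       tumor_attenuation = 0.7,
                       surgery_attenuation = 0.5, surgery_radius = 1L,
                       post_noise_sd = 0.05,
                       grid_dim = c(60L, 60L, 40L), region_voxels = 64L) {
  if (n_volumes <= 0) stop_config("n_volumes must be positive")
  if (any(tr_options <= 0)) stop_config("TRs must be positive")
  if (surgery_attenuation < 0 || surgery_attenuation > 1) {
    stop_config("surgery_attenuation must lie in [0, 1]")
  }
  if (tumor_attenuation < 0 || tumor_attenuation > 1) {
    stop_config("tumor_attenuation must lie in [0, 1]")
  }
  if (backbone_density <= 0 || backbone_density >= 1) {
    stop_config("backbone_density must lie in (0, 1)")
  }
  if (n_empty_labels >= n_atlas_labels) {
    stop_config("n_empty_labels must be smaller than n_atlas_labels")
  }
  if (edge_variance_fraction < 0 || subject_global_fraction < 0 ||
      edge_variance_fraction + subject_global_fraction > 1) {
    stop_config("edge and subject-global variance fractions must be non-negative and sum to at most 1")
  }
  if (plasticity_sd < 0) stop_config("plasticity_sd must be non-negative")
  structure(list(
    n_controls = as.integer(n_controls), n_patients = as.integer(n_patients),
    n_regions_dmn = as.integer(n_regions_dmn), n_volumes = as.integer(n_volumes),
    tr_options = tr_options, bold_noise_sd = bold_noise_sd,
    spectral_tilt = spectral_tilt, tumor_volume_voxels = tumor_volume_voxels,
    overlap_targets = overlap_targets, lesion_labels = lesion_labels,
    periventricular_rate = periventricular_rate,
    n_atlas_labels = as.integer(n_atlas_labels),
    n_empty_labels = as.integer(n_empty_labels),
    backbone_density = backbone_density,
    lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
    edge_variance_fraction = edge_variance_fraction,
    subject_global_fraction = subject_global_fraction,
    plasticity_sd = plasticity_sd,
    spurious_edge_rate = spurious_edge_rate,
    tumor_attenuation = tumor_attenuation,
    surgery_attenuation = surgery_attenuation,
    surgery_radius = as.integer(surgery_radius),
    post_noise_sd = post_noise_sd,
    grid_dim = as.integer(grid_dim), region_voxels = as.integer(region_voxels)),
    class = "sim_config")
}

#' Generate a BOLD series with a known spectral tilt
#'
#' Builds a zero-mean mixture of sinusoids on the discrete frequency
#' comb of the run, with per-frequency power following a power-law
#' envelope |A_f|^2 proportional to f^(-tilt), random phases, unit
#' root-mean-square amplitude, plus white noise. A positive tilt shifts
#' power toward low frequencies, so the expected Dynamics Alteration
#' Score of a tilted series against an untilted reference has the sign
#' of the tilt.
#'
#' @param config A [sim_config()] (supplies `n_volumes` and
#'   `bold_noise_sd`).
#' @param tilt Spectral tilt exponent (0 = flat envelope).
#' @param seed Integer seed; identical seed and config give an identical
#'   series.
#' @param tr_seconds Repetition time (default: first configured
#'   dialect).
#' @param region_id Optional label.
#' @return A [bold_series()].
#' @export
generate_bold <- function(config = sim_config(), tilt = 0, seed = 1L,
                          tr_seconds = config$tr_options[1], region_id = NULL) {
  n <- config$n_volumes
  if (n < 16L) stop_config("need at least 16 volumes for a meaningful spectrum")
  if (tr_seconds <= 0) stop_config("TR must be positive")
  set.seed(as.integer(seed))
  k <- seq_len(floor(n / 2))
  f <- k / (n * tr_seconds)
  amp <- sqrt(f^(-tilt))
  amp <- amp / sqrt(sum(amp^2) / 2)  # unit RMS for the mixture
  phase <- stats::runif(length(k), 0, 2 * pi)
  t_idx <- seq_len(n) - 1L
  x <- drop(cos(outer(t_idx * 2 * pi / n, k) +
                matrix(phase, n, length(k), byrow = TRUE)) %*% amp)
  if (config$bold_noise_sd > 0) {
    x <- x + stats::rnorm(n, sd = config$bold_noise_sd)
  }
  bold_series(x - mean(x), tr_seconds, region_id)
}

neighbors6 <- function(v) {
  matrix(c(v[1] + 1, v[2], v[3], v[1] - 1, v[2], v[3],
           v[1], v[2] + 1, v[3], v[1], v[2] - 1, v[3],
           v[1], v[2], v[3] + 1, v[1], v[2], v[3] - 1),
         ncol = 3, byrow = TRUE)
}

#' Generate tumor and DMN voxel masks
#'
#' DMN regions are disjoint cuboid blobs placed on a lattice inside the
#' abstract voxel grid. The tumor is grown as a single 6-connected blob
#' of the requested volume; growth first claims the requested number of
#' DMN voxels (steering through the inter-region gaps when needed) and
#' then expands outside the DMN, so the resulting overlap fraction
#' |Tumor intersect DMN| / |DMN| matches the request to within one voxel
#' in |DMN|.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for tumor placement.
#' @param tumor_volume Tumor volume in voxels (default 480).
#' @param overlap_target Requested overlap fraction in \[0, 1\]
#'   (default 0).
#' @return List with `tumor_mask` (integer n x 3 matrix) and `dmn_masks`
#'   (list of integer matrices, one per region).
#' @export
generate_masks <- function(config = sim_config(), seed = 1L,
                           tumor_volume = 480L, overlap_target = 0) {
  if (tumor_volume <= 0) stop_config("tumor_volume must be positive")
  dmn <- dmn_region_masks(config)
  dmn_all <- do.call(rbind, dmn)
  n_dmn <- nrow(dmn_all)
  k <- as.integer(round(overlap_target * n_dmn))
  if (k > tumor_volume) {
    stop_config("requested overlap needs %d DMN voxels but the tumor has only %d",
                k, tumor_volume)
  }
  set.seed(as.integer(seed))
  grid <- config$grid_dim
  dmn_keys <- voxel_key(dmn_all)
  in_grid <- function(m) {
    m[m[, 1] >= 1 & m[, 1] <= grid[1] &
      m[, 2] >= 1 & m[, 2] <= grid[2] &
      m[, 3] >= 1 & m[, 3] <= grid[3], , drop = FALSE]
  }

  # seed voxel: the outermost corner of the first region when overlap is
  # requested (so the frontier always reaches non-DMN tissue), the far
  # grid corner otherwise
  start <- if (k > 0) dmn[[1]][which.max(rowSums(dmn[[1]])), ]
           else c(grid[1], grid[2], grid[3])
  tumor <- matrix(as.integer(start), ncol = 3)
  taken <- new.env(hash = TRUE)
  assign(voxel_key(start), TRUE, envir = taken)
  cand <- in_grid(neighbors6(start))
  n_overlap <- as.integer(voxel_key(start) %in% dmn_keys)

  while (nrow(tumor) < tumor_volume) {
    if (nrow(cand) == 0L) stop_config("tumor growth exhausted the grid")
    ck <- voxel_key(cand)
    keep <- !vapply(ck, exists, logical(1), envir = taken)
    cand <- cand[keep, , drop = FALSE]; ck <- ck[keep]
    if (nrow(cand) == 0L) stop_config("tumor growth exhausted the grid")
    in_dmn <- ck %in% dmn_keys
    pick <- if (n_overlap < k) {
      if (any(in_dmn)) {
        which(in_dmn)[1L]
      } else {
        # steer toward the nearest unclaimed DMN voxel
        unclaimed <- dmn_all[!vapply(dmn_keys, exists, logical(1), envir = taken), ,
                             drop = FALSE]
        d2 <- function(v) min(colSums((t(unclaimed) - v)^2))
        which.min(apply(cand, 1L, d2))
      }
    } else {
      out <- which(!in_dmn)
      if (length(out) == 0L) {
        stop_config("cannot reach the requested volume without exceeding the overlap")
      }
      # compact growth: closest to the current centroid
      ctr <- colMeans(tumor)
      out[which.min(colSums((t(cand[out, , drop = FALSE]) - ctr)^2))]
    }
    v <- cand[pick, ]
    tumor <- rbind(tumor, v)
    assign(voxel_key(v), TRUE, envir = taken)
    if (ck[pick] %in% dmn_keys) n_overlap <- n_overlap + 1L
    cand <- rbind(cand[-pick, , drop = FALSE], in_grid(neighbors6(v)))
  }
  dimnames(tumor) <- NULL
  list(tumor_mask = tumor, dmn_masks = dmn)
}

dmn_region_masks <- function(config) {
  side <- ceiling(config$region_voxels^(1 / 3))
  pitch <- side + 1L  # one-voxel gap keeps regions disjoint but bridgeable
  grid <- config$grid_dim
  nx <- max(1L, (grid[1] - 1L) %/% pitch)
  ny <- max(1L, (grid[2] - 1L) %/% pitch)
  nz <- max(1L, (grid[3] - 1L) %/% pitch)
  if (nx * ny * nz < config$n_regions_dmn) {
    stop_config("%d regions of %d voxels do not fit in the %dx%dx%d grid",
                config$n_regions_dmn, config$region_voxels,
                grid[1], grid[2], grid[3])
  }
  cube <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                z = seq_len(side)))[seq_len(config$region_voxels), ,
                                                    drop = FALSE]
  lapply(seq_len(config$n_regions_dmn) - 1L, function(i) {
    ox <- (i %% nx) * pitch
    oy <- ((i %/% nx) %% ny) * pitch
    oz <- (i %/% (nx * ny)) * pitch
    m <- cube + matrix(c(ox, oy, oz), nrow(cube), 3, byrow = TRUE)
    storage.mode(m) <- "integer"
    dimnames(m) <- NULL
    m
  })
}
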