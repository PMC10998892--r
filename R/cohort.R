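#' Generate a synthetic cohort of connectomes and BOLD signals
#'
#' Produces controls and pre/post-surgery patients with a known ground
#' truth. All subjects share a sparse healthy backbone (so a
#' thresholded-average prior is informative); log edge weights decompose
#' into an edge-identity component shared across subjects and a
#' subject-level deviation, so pooled log-weights are exactly
#' N(lognormal_mu, lognormal_sigma^2). Each subject additionally carries
#' a small number of spurious non-backbone edges. Patients receive a
#' lesion: a set of lesion-adjacent nodes drawn from the lobe block
#' named by their lesion label, a tumor voxel mask with a requested DMN
#' overlap, and a post-surgery matrix equal to the pre-surgery matrix
#' with edges within `surgery_radius` graph hops of the lesion nodes
#' multiplied by `surgery_attenuation`, then all edges perturbed by
#' mild multiplicative lognormal noise. The altered edge indices (in
#' vectorized upper-triangle order over active nodes) are recorded as
#' `true_surgery_edges`.
#'
#' Per-region BOLD series use each patient's ground-truth spectral tilt
#' (controls are untilted); repetition times alternate round-robin
#' between the configured dialects.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed; identical seed and config give a
#'   bitwise-identical cohort.
#' @param include_bold Generate per-region BOLD series (default `TRUE`).
#' @param include_masks Generate tumor/DMN voxel masks (default `TRUE`).
#' @return A `synthetic_cohort`: list with `subjects` (list of
#'   `synthetic_subject`), `dmn_masks`, `backbone` (logical edge vector),
#'   `node_labels`, `active_mask`, `config`, `seed`.
#' @export
generate_connectome_cohort <- function(config = sim_config(), seed = 1L,
                                       include_bold = TRUE,
                                       include_masks = TRUE) {
  if (config$n_controls < 2L || config$n_patients < 2L) {
    stop_config("need at least 2 controls and 2 patients")
  }
  seed <- as.integer(seed)
  set.seed(seed)
  n_lab <- config$n_atlas_labels
  labels <- sprintf("label_%03d", seq_len(n_lab))
  active <- rep(TRUE, n_lab)
  if (config$n_empty_labels > 0L) {
    active[seq(n_lab - config$n_empty_labels + 1L, n_lab)] <- FALSE
  }
  n_act <- sum(active)
  n_edges <- n_act * (n_act - 1L) / 2L

  backbone <- stats::runif(n_edges) < config$backbone_density
  sig_edge <- sqrt(config$edge_variance_fraction) * config$lognormal_sigma
  sig_glob <- sqrt(config$subject_global_fraction) * config$lognormal_sigma
  sig_eps <- sqrt(1 - config$edge_variance_fraction -
                    config$subject_global_fraction) * config$lognormal_sigma
  edge_mu <- ifelse(backbone,
                    stats::rnorm(n_edges, config$lognormal_mu, sig_edge), 0)
  # normative post-surgery reorganization, shared across patients
  plasticity <- stats::rnorm(n_edges, 0, config$plasticity_sd)

  # lobe blocks over active nodes, in thirds
  blocks <- split(seq_len(n_act),
                  cut(seq_len(n_act), 3, labels = c("frontal", "temporal", "parietal")))
  g_backbone <- igraph::graph_from_edgelist(
    edge_endpoints(n_act)[backbone, , drop = FALSE], directed = FALSE)
  g_backbone <- igraph::add_vertices(
    g_backbone, max(0L, n_act - igraph::vcount(g_backbone)))

  n_total <- config$n_controls + config$n_patients
  trs <- rep_len(config$tr_options, n_total)
  tilts <- config$spectral_tilt %||%
    seq(-2, 2, length.out = config$n_patients)
  tilts <- rep_len(tilts, config$n_patients)
  volumes <- config$tumor_volume_voxels %||%
    as.integer(round(exp(stats::rnorm(config$n_patients, log(480), 0.5))))
  volumes <- pmax(rep_len(as.integer(volumes), config$n_patients), 8L)
  overlaps <- config$overlap_targets %||%
    stats::runif(config$n_patients, 0, 0.08)
  overlaps <- rep_len(overlaps, config$n_patients)
  lobes <- rep_len(config$lesion_labels %||%
                     c("frontal", "temporal", "parietal"), config$n_patients)
  periv <- stats::runif(config$n_patients) < config$periventricular_rate

  dmn_masks <- if (include_masks) dmn_region_masks(config) else NULL
  region_ids <- sprintf("dmn_%02d", seq_len(config$n_regions_dmn))

  draw_weights <- function() {
    w <- numeric(n_edges)
    gain <- stats::rnorm(1, 0, sig_glob)
    w[backbone] <- exp(edge_mu[backbone] + gain +
                         stats::rnorm(sum(backbone), 0, sig_eps))
    spur <- !backbone & stats::runif(n_edges) < config$spurious_edge_rate
    w[spur] <- stats::rlnorm(sum(spur), config$lognormal_mu,
                             config$lognormal_sigma)
    w
  }
  to_connectome <- function(w) {
    m <- matrix(0, n_lab, n_lab)
    act_idx <- which(active)
    sub <- matrix(0, n_act, n_act)
    sub[upper.tri(sub)] <- w
    sub <- sub + t(sub)
    m[act_idx, act_idx] <- sub
    connectome(m, labels, active, log_scale = FALSE)
  }
  subject_bold <- function(sub_seed, tilt, tr) {
    series <- lapply(seq_len(config$n_regions_dmn), function(r) {
      generate_bold(config, tilt = tilt, seed = sub_seed + r, tr_seconds = tr,
                    region_id = region_ids[r])
    })
    names(series) <- region_ids
    series
  }

  subjects <- vector("list", n_total)
  for (s in seq_len(n_total)) {
    is_patient <- s > config$n_controls
    p <- s - config$n_controls  # patient index (if any)
    sub_seed <- seed + s * 10000L
    set.seed(sub_seed)
    pre_w <- draw_weights()

    if (is_patient) {
      # a lobe label names a fixed anatomical territory: its first k
      # nodes, k scaled by tumor volume (nested territories, so similar
      # tumors produce similar, learnable rewiring patterns)
      block <- blocks[[lobes[p]]]
      k_nodes <- max(2L, min(length(block), as.integer(round(volumes[p] / 160))))
      lesion_nodes <- block[seq_len(k_nodes)]
      hops <- suppressWarnings(
        igraph::distances(g_backbone, v = seq_len(n_act), to = lesion_nodes))
      node_d <- apply(hops, 1L, min)
      ep <- edge_endpoints(n_act)
      in_core <- node_d <= config$surgery_radius - 1L
      # 0, 1 or 2 endpoints inside the resected territory: the
      # attenuation compounds per endpoint, so core edges lose twice as
      # much (in log scale) as boundary edges — the removed-vs-spared
      # gradation of a real resection
      n_in <- as.integer(in_core[ep[, 1]]) + as.integer(in_core[ep[, 2]])
      affected <- n_in >= 1L
      # the tumor itself weakens the lesion territory pre-surgery: the
      # input signature from which the surgery outcome is predictable
      pre_w <- pre_w * config$tumor_attenuation^n_in
      post_w <- pre_w * config$surgery_attenuation^n_in
      if (config$plasticity_sd > 0) {
        post_w <- post_w * exp(plasticity)
      }
      if (config$post_noise_sd > 0) {
        post_w <- post_w * exp(stats::rnorm(n_edges, 0, config$post_noise_sd))
      }
      true_edges <- which(affected & pre_w > 0)
      masks <- if (include_masks) {
        generate_masks(config, seed = sub_seed + 1L,
                       tumor_volume = volumes[p],
                       overlap_target = overlaps[p])
      } else NULL
      subjects[[s]] <- structure(list(
        subject_id = sprintf("PAT%02d", p), role = "patient",
        tr_seconds = trs[s], true_tilt = tilts[p],
        lesion_label = lobes[p], periventricular = periv[p],
        tumor_volume_voxels = volumes[p],
        bold = if (include_bold) subject_bold(sub_seed + 100L, tilts[p], trs[s]) else NULL,
        tumor_mask = masks$tumor_mask,
        pre_connectome = to_connectome(pre_w),
        post_connectome = to_connectome(post_w),
        true_surgery_edges = true_edges,
        lesion_nodes = lesion_nodes), class = "synthetic_subject")
    } else {
      subjects[[s]] <- structure(list(
        subject_id = sprintf("CON%02d", s), role = "control",
        tr_seconds = trs[s], true_tilt = 0,
        lesion_label = NA_character_, periventricular = NA,
        tumor_volume_voxels = NA_integer_,
        bold = if (include_bold) subject_bold(sub_seed + 100L, 0, trs[s]) else NULL,
        tumor_mask = NULL,
        pre_connectome = to_connectome(pre_w),
        post_connectome = NULL,
        true_surgery_edges = integer(0),
        lesion_nodes = integer(0)), class = "synthetic_subject")
    }
  }
  structure(list(subjects = subjects, dmn_masks = dmn_masks,
                 backbone = backbone, node_labels = labels,
                 active_mask = active, config = config, seed = seed),
            class = "synthetic_cohort")
}

# endpoints (i, j), i < j, of the vectorized upper triangle in R's
# column-major upper.tri order, for n nodes
edge_endpoints <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d controls + %d patients, %d atlas labels (%d active), seed %d\n",
              x$config$n_controls, x$config$n_patients,
              x$config$n_atlas_labels, sum(x$active_mask), x$seed))
  invisible(x)
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject> %s (%s)%s\n", x$subject_id, x$role,
              if (x$role == "patient")
                sprintf(", tilt %.2f, lesion %s, %d surgery edges",
                        x$true_tilt, x$lesion_label,
                        length(x$true_surgery_edges)) else ""))
  invisible(x)
}

#' Split a cohort into controls and patients
#'
#' @param cohort A `synthetic_cohort`.
#' @return List with `controls` and `patients`.
#' @export
split_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  roles <- vapply(cohort$subjects, `[[`, character(1), "role")
  list(controls = cohort$subjects[roles == "control"],
       patients = cohort$subjects[roles == "patient"])
}
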