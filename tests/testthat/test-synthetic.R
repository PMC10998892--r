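test_that("BOLD generation is deterministic and validates its inputs", {
  cfg <- sim_config()
  a <- generate_bold(cfg, tilt = 1.5, seed = 7)
  b <- generate_bold(cfg, tilt = 1.5, seed = 7)
  expect_identical(a$values, b$values)
  expect_equal(mean(a$values), 0, tolerance = 1e-12)
  expect_error(generate_bold(sim_config(n_volumes = 8), seed = 1),
               class = "dasnet_config_error")
  expect_error(generate_bold(cfg, seed = 1, tr_seconds = -1),
               class = "dasnet_config_error")
})

test_that("spectral tilt shifts cumulative power in the expected direction", {
  cfg <- sim_config()
  ref <- generate_bold(cfg, tilt = 0, seed = 999)
  signs <- vapply(1:30, function(i) {
    slow <- generate_bold(cfg, tilt = 2, seed = i)
    fast <- generate_bold(cfg, tilt = -2, seed = 500 + i)
    c(sign(das_between_series(slow, ref)$value),
      sign(das_between_series(fast, ref)$value))
  }, numeric(2))
  expect_gte(mean(signs[1, ] > 0), 0.9)
  expect_gte(mean(signs[2, ] < 0), 0.9)
})

test_that("mask generation hits the requested overlap exactly", {
  cfg <- small_sim()
  m0 <- generate_masks(cfg, seed = 1, tumor_volume = 60, overlap_target = 0)
  expect_equal(nrow(m0$tumor_mask), 60)
  expect_length(m0$dmn_masks, 4)
  ov0 <- tumor_dmn_overlap(m0$tumor_mask, do.call(rbind, m0$dmn_masks))
  expect_equal(ov0$value, 0)

  dmn_all <- do.call(rbind, m0$dmn_masks)
  m4 <- generate_masks(cfg, seed = 2, tumor_volume = 90, overlap_target = 0.4)
  ov4 <- tumor_dmn_overlap(m4$tumor_mask, dmn_all)
  expect_equal(ov4$value, round(0.4 * nrow(dmn_all)) / nrow(dmn_all))
  # brute-force set arithmetic agrees
  inter <- sum(voxel_key(m4$tumor_mask) %in% voxel_key(dmn_all))
  expect_equal(ov4$tumor_voxels_in_dmn, inter)
})

test_that("full DMN coverage yields overlap 1; infeasible requests error", {
  cfg <- sim_config(n_regions_dmn = 2L, region_voxels = 8L,
                    grid_dim = c(20L, 20L, 12L))
  dmn_all <- do.call(rbind, generate_masks(cfg, 1, 10, 0)$dmn_masks)
  full <- generate_masks(cfg, seed = 3, tumor_volume = 60, overlap_target = 1)
  expect_equal(tumor_dmn_overlap(full$tumor_mask, dmn_all)$value, 1)
  expect_error(generate_masks(cfg, seed = 1, tumor_volume = 10,
                              overlap_target = 1),
               class = "dasnet_config_error")
})

test_that("cohort generation is deterministic and satisfies invariants", {
  cfg <- small_sim()
  a <- generate_connectome_cohort(cfg, seed = 3)
  b <- generate_connectome_cohort(cfg, seed = 3)
  expect_identical(a$subjects, b$subjects)
  for (s in a$subjects) {
    w <- s$pre_connectome$weights
    expect_equal(max(abs(w - t(w))), 0)
    expect_equal(max(abs(diag(w))), 0)
    expect_true(all(w >= 0))
    expect_true(all(w[!a$active_mask, ] == 0))
  }
  expect_equal(sum(a$active_mask), 22)
  # default atlas dialect: 166 active of 170
  def <- generate_connectome_cohort(sim_config(n_controls = 2, n_patients = 2),
                                    seed = 1, include_bold = FALSE,
                                    include_masks = FALSE)
  expect_equal(sum(def$active_mask), 166)
})

test_that("surgery operator honours its identity and removal limits", {
  quiet <- small_sim(surgery_attenuation = 1, tumor_attenuation = 1,
                     post_noise_sd = 0, plasticity_sd = 0)
  co <- generate_connectome_cohort(quiet, seed = 5, include_bold = FALSE,
                                   include_masks = FALSE)
  pat <- split_cohort(co)$patients
  for (p in pat) {
    expect_equal(p$post_connectome$weights, p$pre_connectome$weights)
  }
  ablate <- small_sim(surgery_attenuation = 0, post_noise_sd = 0,
                      plasticity_sd = 0)
  co0 <- generate_connectome_cohort(ablate, seed = 5, include_bold = FALSE,
                                    include_masks = FALSE)
  for (p in split_cohort(co0)$patients) {
    expect_gt(length(p$true_surgery_edges), 0)
    post <- vectorize_edges(p$post_connectome)
    expect_true(all(post[p$true_surgery_edges] == 0))
  }
})

test_that("controls carry no post-surgery data and patients carry masks", {
  co <- generate_connectome_cohort(small_sim(), seed = 2)
  sp <- split_cohort(co)
  for (ctl in sp$controls) {
    expect_null(ctl$post_connectome)
    expect_null(ctl$tumor_mask)
  }
  for (p in sp$patients) {
    expect_false(is.null(p$post_connectome))
    expect_gt(nrow(p$tumor_mask), 0)
  }
})

test_that("pooled log-weights match the configured lognormal moments", {
  # controls only: patients' pre-surgery matrices carry the tumor
  # attenuation by construction
  cfg <- sim_config(n_controls = 50L, n_patients = 2L)
  co <- generate_connectome_cohort(cfg, seed = 11, include_bold = FALSE,
                                   include_masks = FALSE)
  logs <- unlist(lapply(split_cohort(co)$controls, function(s) {
    w <- vectorize_edges(s$pre_connectome)[co$backbone]
    log(w[w > 0])
  }))
  n <- length(logs)
  expect_gt(n, 1e5 * 0.9)
  # standard errors must respect the hierarchical design: edge means are
  # shared across subjects and the per-subject gain is shared across
  # edges, so the i.i.d. formulas understate the estimator variance
  n_edges_bb <- sum(co$backbone)
  s2 <- cfg$lognormal_sigma^2
  se_mean <- sqrt(cfg$edge_variance_fraction * s2 / n_edges_bb +
                    cfg$subject_global_fraction * s2 / cfg$n_controls +
                    (1 - cfg$edge_variance_fraction -
                       cfg$subject_global_fraction) * s2 / n)
  expect_lt(abs(mean(logs) - cfg$lognormal_mu), 3 * se_mean)
  # jackknife over subjects for the pooled-variance standard error
  per_subject <- lapply(split_cohort(co)$controls, function(s) {
    w <- vectorize_edges(s$pre_connectome)[co$backbone]
    log(w[w > 0])
  })
  jk <- vapply(seq_along(per_subject), function(i) {
    var(unlist(per_subject[-i]))
  }, numeric(1))
  m <- length(jk)
  se_var <- sqrt((m - 1) / m * sum((jk - mean(jk))^2))
  expect_lt(abs(var(logs) - s2), 3 * se_var)
  # unimodality on the log scale (sanity precondition for divergences)
  d <- density(logs)
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1
  strong <- sum(d$y[peaks] > 0.2 * max(d$y))
  expect_equal(strong, 1)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(surgery_attenuation = 1.2), class = "dasnet_config_error")
  expect_error(sim_config(backbone_density = 0), class = "dasnet_config_error")
  expect_error(sim_config(n_volumes = 0), class = "dasnet_config_error")
  expect_error(sim_config(edge_variance_fraction = 0.8,
                          subject_global_fraction = 0.3),
               class = "dasnet_config_error")
  expect_error(generate_connectome_cohort(small_sim(n_controls = 1), seed = 1),
               class = "dasnet_config_error")
})
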