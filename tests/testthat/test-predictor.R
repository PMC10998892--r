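# small cohort shared across predictor tests
cohort22 <- generate_connectome_cohort(small_sim(), seed = 42,
                                       include_bold = FALSE,
                                       include_masks = FALSE)
parts22 <- split_cohort(cohort22)
prior22 <- build_anatomical_prior(lapply(parts22$controls, `[[`, "pre_connectome"),
                                  tau = 0.5)
loo22 <- lapply(parts22$patients, function(s) {
  list(id = s$subject_id, pre = s$pre_connectome, post = s$post_connectome)
})

test_that("edge vectorization follows upper-triangle order and round-trips", {
  m3 <- matrix(0, 3, 3)
  m3[1, 2] <- m3[2, 1] <- 12
  m3[1, 3] <- m3[3, 1] <- 13
  m3[2, 3] <- m3[3, 2] <- 23
  expect_equal(vectorize_edges(connectome(m3)), c(12, 13, 23))
  c170 <- connectome(matrix(0, 170, 170),
                     active_mask = c(rep(TRUE, 166), rep(FALSE, 4)))
  expect_length(vectorize_edges(c170), 13695)
  r <- log_transform(random_connectome(9, seed = 2))
  back <- devectorize_edges(vectorize_edges(r), r, log_scale = TRUE)
  expect_identical(back$weights, r$weights)
  expect_error(devectorize_edges(1:5, r), class = "dasnet_config_error")
})

test_that("anatomical prior counts presence fractions and thresholds them", {
  base <- matrix(0, 4, 4)
  mk <- function(edges) {
    m <- base
    for (e in edges) m[e[1], e[2]] <- m[e[2], e[1]] <- 1
    connectome(m)
  }
  pool <- list(mk(list(c(1, 2), c(1, 3))), mk(list(c(1, 2))),
               mk(list(c(1, 2), c(1, 3))), mk(list(c(1, 2), c(1, 3))),
               mk(list(c(1, 2))), mk(list(c(1, 2))))
  pr <- build_anatomical_prior(pool, tau = 0.6)
  # edge order: (1,2), (1,3), (2,3), (1,4), (2,4), (3,4)
  expect_equal(pr$edge_weights[1], 1)     # in all six
  expect_true(pr$support[1])
  expect_equal(pr$edge_weights[2], 0.5)   # in three of six
  expect_false(pr$support[2])             # 0.5 < 0.6 dropped
  expect_equal(pr$edge_weights[3], 0)
  expect_false(pr$support[3])
  expect_error(build_anatomical_prior(pool[1]), class = "dasnet_config_error")
  odd <- mk(list(c(1, 2)))
  odd$node_labels[2] <- "zzz"
  expect_error(build_anatomical_prior(list(pool[[1]], odd)),
               class = "dasnet_data_error")
})

test_that("prior gating forces exact zeros for every model kind", {
  cfg <- predictor_config(hidden_units = 16L, seed = 3)
  pairs <- lapply(loo22[-1], function(s) {
    list(pre = vectorize_edges(log_transform(s$pre)),
         post = vectorize_edges(log_transform(s$post)))
  })
  x <- vectorize_edges(log_transform(loo22[[1]]$pre))
  off <- !prior22$support
  for (model in list(fcnet_train(pairs, prior22, cfg),
                     huber_benchmark(pairs, prior22),
                     null_benchmark(prior22, seed = 5, hidden = 16))) {
    p <- predict(model, x)
    expect_true(all(p$raw[off] == 0))
    expect_true(all(p$filtered[off] == 0))
  }
})

test_that("training is deterministic and learns a self-map", {
  idp <- identity_prior(random_connectome(24, seed = 300))
  set.seed(77)
  pairs <- lapply(1:6, function(i) {
    v <- vectorize_edges(log_transform(
      random_connectome(24, density = 0.4, seed = 300 + i)))
    list(pre = v, post = v)
  })
  held <- vectorize_edges(log_transform(
    random_connectome(24, density = 0.4, seed = 400)))
  cfg <- predictor_config(hidden_units = 32L, seed = 9)
  m1 <- fcnet_train(pairs, idp, cfg)
  m2 <- fcnet_train(pairs, idp, cfg)
  expect_identical(m1$training_curve, m2$training_curve)
  expect_identical(m1$parameters$W2, m2$parameters$W2)
  barely <- fcnet_train(pairs, idp,
                        predictor_config(hidden_units = 32L, seed = 9,
                                         epochs = 1L, val_every = 1L))
  mse <- function(m) mean((predict(m, held)$raw - held)^2)
  expect_lt(mse(m1), mse(barely))
  expect_lt(tail(m1$training_curve, 1), m1$training_curve[1])
})

test_that("the Huber benchmark recovers exact and contaminated slopes", {
  set.seed(55)
  pre <- lapply(1:4, function(i) {
    vectorize_edges(log_transform(random_connectome(24, density = 0.5,
                                                    seed = 500 + i)))
  })
  tmpl <- random_connectome(24, seed = 500)
  idp <- identity_prior(tmpl)
  exact <- lapply(pre, function(v) list(pre = v, post = 2 * v))
  h <- huber_benchmark(exact, idp)
  expect_equal(h$parameters$slope, 2, tolerance = 1e-6)
  expect_equal(h$parameters$intercept, 0, tolerance = 1e-6)

  contaminated <- lapply(pre, function(v) {
    post <- v
    n <- length(v)
    bad <- sample(n, round(0.01 * n))
    post[bad] <- post[bad] + 50
    list(pre = v, post = post)
  })
  hc <- huber_benchmark(contaminated, idp)
  X <- unlist(lapply(contaminated, `[[`, "pre"))
  Y <- unlist(lapply(contaminated, `[[`, "post"))
  ols_slope <- coef(lm(Y ~ X))[2]
  expect_lt(abs(hc$parameters$slope - 1), abs(ols_slope - 1))
  degen <- lapply(pre[1:2], function(v) list(pre = 0 * v, post = 0 * v))
  expect_error(huber_benchmark(degen, idp), class = "dasnet_numeric_error")
})

test_that("the null generator is seeded and never trained", {
  n1 <- null_benchmark(prior22, seed = 8, hidden = 16)
  n2 <- null_benchmark(prior22, seed = 8, hidden = 16)
  x <- vectorize_edges(log_transform(loo22[[1]]$pre))
  expect_identical(predict(n1, x)$raw, predict(n2, x)$raw)
  expect_null(n1$training_curve)
})

test_that("leave-one-out produces one fold per subject with consistent metrics", {
  cfg <- predictor_config(hidden_units = 16L, seed = 4)
  res <- loo_cross_validate(loo22[1:3], prior22, cfg, "huber",
                            return_predictions = TRUE)
  expect_equal(nrow(res), 3)
  expect_setequal(res$left_out_id, vapply(loo22[1:3], `[[`, "", "id"))
  # compositional consistency: fold metrics equal standalone calls
  preds <- attr(res, "predictions")
  ins <- attr(res, "inputs")
  for (i in 1:3) {
    direct <- reconstruction_metrics(preds[[i]]$raw, ins[[i]]$post)
    expect_equal(res$mse[i], direct$mse, tolerance = 1e-12)
    expect_equal(res$mae[i], direct$mae, tolerance = 1e-12)
    expect_equal(res$pcc[i], direct$pcc, tolerance = 1e-12)
    expect_equal(res$cs[i], direct$cs, tolerance = 1e-12)
    wd <- weight_distribution_pair(preds[[i]]$filtered, ins[[i]]$post)
    expect_equal(res$kl[i], kl_divergence(wd$p, wd$q), tolerance = 1e-12)
    expect_equal(res$js[i], js_divergence(wd$p, wd$q), tolerance = 1e-12)
  }
  expect_error(loo_cross_validate(loo22[1:2], prior22, cfg, "huber"),
               class = "dasnet_config_error")
})

test_that("negative log-weight predictions are filtered from the output matrix", {
  n1 <- null_benchmark(prior22, seed = 12, hidden = 16)
  x <- vectorize_edges(log_transform(loo22[[2]]$pre))
  p <- predict(n1, x)
  small <- p$raw != 0 & expm1(p$raw) < 1
  expect_true(any(small))  # negatives exist for a random map
  expect_true(all(p$filtered[small] == 0))
  kept <- p$filtered != 0
  expect_true(all(expm1(p$filtered[kept]) >= 1))
  m <- p$connectome$weights
  expect_equal(m, t(m))
  expect_equal(max(abs(diag(m))), 0)
})

test_that("predictor configuration is validated", {
  expect_error(predictor_config(val_fraction = 0), class = "dasnet_config_error")
  expect_error(predictor_config(epochs = 5, val_every = 20),
               class = "dasnet_config_error")
  expect_error(fcnet_train(list(), prior22), class = "dasnet_config_error")
})
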