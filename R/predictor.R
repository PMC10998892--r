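#' Vectorize / devectorize connectome edges
#'
#' Flattens the upper triangle (i < j) over active nodes into an edge
#' vector in R's column-major upper-triangle order; with the default
#' 170-label / 4-empty-label atlas dialect this yields 13695 edges.
#' `devectorize_edges()` restores a symmetric zero-diagonal matrix with
#' zeros on inactive nodes.
#'
#' @param c A `connectome`.
#' @return Numeric edge vector.
#' @export
vectorize_edges <- function(c) {
  stopifnot(inherits(c, "connectome"))
  act <- which(c$active_mask)
  sub <- c$weights[act, act, drop = FALSE]
  sub[upper.tri(sub)]
}

#' @rdname vectorize_edges
#' @param vec Edge vector of length n_active * (n_active - 1) / 2.
#' @param template A `connectome` (or `anatomical_prior`) supplying node
#'   labels and active mask.
#' @param log_scale Scale flag of the rebuilt connectome.
#' @export
devectorize_edges <- function(vec, template, log_scale = TRUE) {
  labels <- template$node_labels
  active <- template$active_mask
  n_act <- sum(active)
  expected <- n_act * (n_act - 1L) / 2L
  if (length(vec) != expected) {
    stop_config("edge vector has length %d, expected %d", length(vec), expected)
  }
  sub <- matrix(0, n_act, n_act)
  sub[upper.tri(sub)] <- vec
  sub <- sub + t(sub)
  m <- matrix(0, length(labels), length(labels))
  act_idx <- which(active)
  m[act_idx, act_idx] <- sub
  connectome(m, labels, active, log_scale = log_scale)
}

#' Build an anatomical prior from a healthy cohort
#'
#' Per-edge plausibility is the fraction of healthy subjects whose
#' native weight on that edge is positive; the support retains edges
#' with fraction at least `tau`. This thresholded average controls the
#' inclusion or exclusion of spurious connections, and the prior gates
#' every predictor's output (edges outside the support are forced to
#' exactly zero).
#'
#' @param healthy List of >= 2 native-scale `connectome` objects on
#'   common labels.
#' @param tau Retention threshold in \[0, 1\] (default 0.5: present in
#'   at least half of the controls).
#' @return An `anatomical_prior`: `edge_weights`, `tau`, `support`,
#'   `gate` (`edge_weights * support`), `node_labels`, `active_mask`.
#' @export
build_anatomical_prior <- function(healthy, tau = 0.5) {
  if (length(healthy) < 2L) stop_config("need at least 2 healthy connectomes")
  ref <- healthy[[1]]
  for (h in healthy) {
    stopifnot(inherits(h, "connectome"))
    if (h$log_scale) stop_data("prior is built from native-scale connectomes")
    if (!identical(h$node_labels, ref$node_labels) ||
        !identical(h$active_mask, ref$active_mask)) {
      stop_data("healthy connectomes have mismatched labels")
    }
  }
  present <- vapply(healthy, function(h) as.numeric(vectorize_edges(h) > 0),
                    numeric(length(vectorize_edges(ref))))
  frac <- rowMeans(present)
  support <- frac >= tau
  structure(list(edge_weights = frac, tau = tau, support = support,
                 gate = frac * support,
                 node_labels = ref$node_labels,
                 active_mask = ref$active_mask),
            class = "anatomical_prior")
}

#' An all-pass prior (identity gating)
#'
#' Every edge has plausibility 1; useful for ablations and tests.
#'
#' @param template A `connectome` supplying labels and active mask.
#' @return An `anatomical_prior`.
#' @export
identity_prior <- function(template) {
  n_act <- sum(template$active_mask)
  n_edges <- n_act * (n_act - 1L) / 2L
  structure(list(edge_weights = rep(1, n_edges), tau = 0,
                 support = rep(TRUE, n_edges), gate = rep(1, n_edges),
                 node_labels = template$node_labels,
                 active_mask = template$active_mask),
            class = "anatomical_prior")
}

#' @export
print.anatomical_prior <- function(x, ...) {
  cat(sprintf("<anatomical_prior> %d edges, tau = %.2f, %d retained (%.1f%%)\n",
              length(x$edge_weights), x$tau, sum(x$support),
              100 * mean(x$support)))
  invisible(x)
}

#' Predictor training configuration
#'
#' @param hidden_units Hidden-layer width (default 256; the width is a
#'   free design choice in the small-sample regime).
#' @param learning_rate SGD learning rate (default 0.01).
#' @param epochs Training epochs (default 100).
#' @param val_fraction Fraction of training subjects held out for
#'   validation (default 0.2).
#' @param val_every Record validation loss every this many epochs
#'   (default 20).
#' @param batch_size Samples per gradient step (default 1: per-sample
#'   stochastic gradient descent; set to the training-set size for
#'   full-batch steps).
#' @param seed Integer seed controlling weight initialization and epoch
#'   shuffles.
#' @param output_filter_native_weight Predicted edges whose native
#'   weight exp(x) - 1 falls below this value are filtered to zero in
#'   the output matrix (default 1.0: less than one streamline). Raw
#'   predictions are kept alongside for metric computation.
#' @return A `predictor_config` list.
#' @export
predictor_config <- function(hidden_units = 256L, learning_rate = 0.01,
                             epochs = 100L, val_fraction = 0.2,
                             val_every = 20L, batch_size = 1L, seed = 1L,
                             output_filter_native_weight = 1.0) {
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop_config("val_fraction must lie in (0, 1)")
  }
  if (epochs < val_every) stop_config("epochs must be >= val_every")
  structure(list(hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 val_fraction = val_fraction, val_every = as.integer(val_every),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 output_filter_native_weight = output_filter_native_weight),
            class = "predictor_config")
}

pairs_to_matrices <- function(pairs) {
  X <- do.call(rbind, lapply(pairs, function(p) as.numeric(p$pre)))
  Y <- do.call(rbind, lapply(pairs, function(p) as.numeric(p$post)))
  list(X = X, Y = Y)
}

check_pairs <- function(pairs, prior) {
  n_edges <- length(prior$edge_weights)
  for (p in pairs) {
    if (length(p$pre) != n_edges || length(p$post) != n_edges) {
      stop_config("pair edge vectors must match the prior length (%d)", n_edges)
    }
  }
}

#' Train the one-hidden-layer connectome predictor (FCNET)
#'
#' A fully connected network with one rectified-linear hidden layer and
#' a linear output (so negative log-weights are representable) maps the
#' pre-surgery edge vector to the post-surgery edge vector. The output
#' is gated elementwise by the anatomical prior *inside* the mean
#' squared error loss, so the prior participates in backpropagation:
#' highly plausible connections dominate the loss while edges outside
#' the support are forced to zero and receive no gradient. Weights are
#' optimized by stochastic gradient descent (per-sample by default)
#' with an 80/20 train/validation split of the supplied pairs and
#' validation loss recorded every `val_every` epochs. No regularization
#' is applied. Fully deterministic under `cfg$seed`.
#'
#' @param pairs List of training pairs, each `list(pre = , post = )`,
#'   log-scale edge vectors.
#' @param prior An `anatomical_prior` of matching length.
#' @param cfg A [predictor_config()].
#' @return A `trained_predictor` of kind `"fcnet"`.
#' @export
fcnet_train <- function(pairs, prior, cfg = predictor_config()) {
  stopifnot(inherits(prior, "anatomical_prior"))
  if (length(pairs) < 2L) stop_config("need at least 2 training pairs")
  check_pairs(pairs, prior)
  m <- pairs_to_matrices(pairs)
  n <- nrow(m$X); E <- ncol(m$X); H <- cfg$hidden_units

  set.seed(cfg$seed)
  n_val <- min(n - 1L, max(1L, round(cfg$val_fraction * n)))
  if (n_val < 1L || n - n_val < 1L) stop_config("degenerate train/validation split")
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  n_tr <- length(tr_idx)

  # scaled-uniform fan-in initialization keeps early SGD steps small
  # enough at lr ~ 0.01 that rectified units stay alive
  W1 <- matrix(stats::runif(H * E, -1, 1) / sqrt(E), H, E)
  b1 <- stats::runif(H, -1, 1) / sqrt(E)
  W2 <- matrix(stats::runif(E * H, -1, 1) / sqrt(H), E, H)
  b2 <- stats::runif(E, -1, 1) / sqrt(H)
  order <- t(vapply(seq_len(cfg$epochs),
                    function(i) sample.int(n_tr), integer(n_tr)))
  storage.mode(order) <- "integer"

  # the gate zeroes every gradient outside the prior support, so the
  # output layer is trained in support-restricted form; the constant
  # off-support contribution to the loss is carried separately
  sup <- prior$support
  off_const <- function(Y) rowSums(Y[, !sup, drop = FALSE]^2)
  fit <- fcnet_sgd_cpp(m$X[tr_idx, , drop = FALSE],
                       m$Y[tr_idx, sup, drop = FALSE],
                       off_const(m$Y[tr_idx, , drop = FALSE]),
                       m$X[val_idx, , drop = FALSE],
                       m$Y[val_idx, sup, drop = FALSE],
                       off_const(m$Y[val_idx, , drop = FALSE]),
                       prior$gate[sup], W1, b1, W2[sup, , drop = FALSE], b2[sup],
                       cfg$learning_rate, cfg$epochs, cfg$val_every,
                       min(cfg$batch_size, n_tr), order, E)
  W2[sup, ] <- fit$W2s
  b2[sup] <- fit$b2s
  structure(list(kind = "fcnet",
                 parameters = list(W1 = fit$W1, b1 = as.numeric(fit$b1),
                                   W2 = W2, b2 = b2),
                 prior = prior, config = cfg,
                 training_curve = fit$training_curve,
                 validation_curve = fit$validation_curve,
                 validation_epochs = fit$validation_epochs),
            class = "trained_predictor")
}

#' Huber benchmark regressor
#'
#' A single robust linear map fitted on pooled (pre-edge, post-edge)
#' scalar pairs across all training subjects and all edges in the prior
#' support, using Huber M-estimation (transition constant 1.35, the
#' conventional 95%-efficiency value), chosen for robustness to the
#' gross outliers heterogeneous connectomes produce. Predictions are
#' gated by the prior exactly as the neural predictor's. A pooled
#' scalar fit is used because per-edge fits are unidentifiable with a
#' handful of subjects and ~10^4 outputs.
#'
#' @inheritParams fcnet_train
#' @param k Huber transition constant (default 1.345).
#' @return A `trained_predictor` of kind `"huber"` with `slope` and
#'   `intercept` parameters.
#' @export
huber_benchmark <- function(pairs, prior, k = 1.345) {
  stopifnot(inherits(prior, "anatomical_prior"))
  if (length(pairs) < 2L) stop_config("need at least 2 training pairs")
  check_pairs(pairs, prior)
  m <- pairs_to_matrices(pairs)
  x <- as.numeric(m$X[, prior$support, drop = FALSE])
  y <- as.numeric(m$Y[, prior$support, drop = FALSE])
  if (length(x) == 0L || stats::sd(x) == 0) {
    stop_numeric("pooled training edges are degenerate: Huber fit impossible")
  }
  ols <- stats::lm.fit(cbind(1, x), y)
  coefs <- if (max(abs(ols$residuals)) <= 1e-8 * max(1, stats::sd(y))) {
    ols$coefficients  # exact linear relation: the robust fit coincides
  } else {
    stats::coef(MASS::rlm(x = cbind(1, x), y = y, psi = MASS::psi.huber,
                          k = k, maxit = 100))
  }
  structure(list(kind = "huber",
                 parameters = list(intercept = unname(coefs[1]),
                                   slope = unname(coefs[2])),
                 prior = prior, config = NULL,
                 training_curve = NULL),
            class = "trained_predictor")
}

#' Null benchmark: an untrained linear generator
#'
#' A linear map with randomly initialized, never-updated parameters,
#' gated by the same anatomical prior as the trained models. The map is
#' stored in factored form (two rectangular matrices through a hidden
#' dimension) so that the full edge-by-edge matrix is never
#' materialized; its output scale matches the input's root mean square.
#'
#' @param prior An `anatomical_prior`.
#' @param seed Integer seed; identical seeds give identical predictions.
#' @param hidden Factorization width (default 256).
#' @return A `trained_predictor` of kind `"null"`.
#' @export
null_benchmark <- function(prior, seed = 1L, hidden = 256L) {
  stopifnot(inherits(prior, "anatomical_prior"))
  E <- length(prior$edge_weights)
  set.seed(as.integer(seed))
  structure(list(kind = "null",
                 parameters = list(
                   B = matrix(stats::rnorm(hidden * E, sd = 1 / sqrt(E)), hidden, E),
                   A = matrix(stats::rnorm(E * hidden, sd = 1 / sqrt(hidden)), E, hidden)),
                 prior = prior, config = NULL,
                 training_curve = NULL),
            class = "trained_predictor")
}

#' @export
print.trained_predictor <- function(x, ...) {
  cat(sprintf("<trained_predictor> kind = %s, %d edges (%d in prior support)\n",
              x$kind, length(x$prior$edge_weights), sum(x$prior$support)))
  invisible(x)
}

#' Predict a post-surgery connectome
#'
#' Applies the model to a pre-surgery edge vector (log scale), gates
#' the raw output by the anatomical prior, and filters entries whose
#' native weight exp(x) - 1 falls below the configured cutoff to zero —
#' negative log-weight predictions therefore vanish from the output
#' matrix while remaining visible in the raw vector used for metrics.
#'
#' @param object A `trained_predictor`.
#' @param pre Pre-surgery `connectome` in log scale, or a log-scale edge
#'   vector.
#' @param output_filter_native_weight Filter cutoff in native weight
#'   units (default: the training configuration's value, or 1.0).
#' @param ... Unused.
#' @return List with `raw` (gated, unfiltered edge vector), `filtered`
#'   (edge vector after the native-weight filter) and `connectome` (the
#'   filtered, symmetric, log-scale matrix).
#' @export
predict.trained_predictor <- function(object, pre,
                                      output_filter_native_weight = NULL, ...) {
  if (inherits(pre, "connectome")) {
    if (!pre$log_scale) stop_data("predictor inputs must be log(1+w) scaled")
    x <- vectorize_edges(pre)
  } else {
    x <- as.numeric(pre)
  }
  E <- length(object$prior$edge_weights)
  if (length(x) != E) stop_config("input has %d edges, expected %d", length(x), E)
  p <- object$parameters
  raw <- switch(object$kind,
    fcnet = as.numeric(p$W2 %*% pmax(p$W1 %*% x + p$b1, 0) + p$b2),
    huber = p$intercept + p$slope * x,
    null = as.numeric(p$A %*% (p$B %*% x)),
    stop_config("unknown predictor kind '%s'", object$kind))
  raw <- raw * object$prior$gate
  cutoff <- output_filter_native_weight %||%
    (object$config$output_filter_native_weight %||% 1.0)
  filtered <- raw
  filtered[expm1(filtered) < cutoff] <- 0
  list(raw = raw, filtered = filtered,
       connectome = devectorize_edges(filtered, object$prior, log_scale = TRUE))
}

#' Leave-one-out cross-validation of a connectome predictor
#'
#' One fold per subject: the model is trained on all other pre/post
#' pairs and evaluated on the left-out pair with six metrics — MSE,
#' MAE, Pearson correlation and cosine similarity on the raw flattened
#' log-scale vectors, plus base-2 Kullback-Leibler and Jensen-Shannon
#' divergences between the weight probability distributions of the
#' filtered predicted graph and the ground truth. Per-fold seeds are
#' derived deterministically from `cfg$seed`.
#'
#' @param cohort List of subjects, each `list(id = , pre = , post = )`
#'   with `connectome` objects (native scale; log-transformed
#'   internally) or log-scale edge vectors.
#' @param prior An `anatomical_prior`.
#' @param cfg A [predictor_config()].
#' @param model_kind `"fcnet"`, `"huber"` or `"null"`.
#' @param return_predictions Also attach the per-fold predictions and
#'   the vectorized inputs as attributes `predictions` and `inputs`
#'   (default `FALSE`).
#' @return A data frame of fold results: `left_out_id`, `mse`, `mae`,
#'   `pcc`, `cs`, `kl`, `js`.
#' @export
loo_cross_validate <- function(cohort, prior, cfg = predictor_config(),
                               model_kind = c("fcnet", "huber", "null"),
                               return_predictions = FALSE) {
  model_kind <- match.arg(model_kind)
  if (length(cohort) < 3L) stop_config("LOO needs a cohort of at least 3")
  vecs <- lapply(cohort, function(s) {
    pre <- if (inherits(s$pre, "connectome")) {
      vectorize_edges(if (s$pre$log_scale) s$pre else log_transform(s$pre))
    } else as.numeric(s$pre)
    post <- if (inherits(s$post, "connectome")) {
      vectorize_edges(if (s$post$log_scale) s$post else log_transform(s$post))
    } else as.numeric(s$post)
    list(id = s$id %||% s$subject_id, pre = pre, post = post)
  })
  res <- lapply(seq_along(vecs), function(i) {
    train <- vecs[-i]
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + i
    model <- switch(model_kind,
      fcnet = fcnet_train(train, prior, fold_cfg),
      huber = huber_benchmark(train, prior),
      null = null_benchmark(prior, seed = fold_cfg$seed))
    pred <- predict(model, vecs[[i]]$pre,
                    output_filter_native_weight = cfg$output_filter_native_weight)
    list(metrics = fold_metrics(pred, vecs[[i]]$post, vecs[[i]]$id),
         prediction = if (return_predictions) pred)
  })
  metrics <- do.call(rbind, lapply(res, `[[`, "metrics"))
  if (!return_predictions) return(metrics)
  structure(metrics,
            predictions = lapply(res, `[[`, "prediction"),
            inputs = vecs)
}

fold_metrics <- function(pred, truth_vec, id) {
  rm_ <- reconstruction_metrics(pred$raw, truth_vec)
  wd <- weight_distribution_pair(pred$filtered, truth_vec)
  data.frame(left_out_id = id, mse = rm_$mse, mae = rm_$mae,
             pcc = rm_$pcc, cs = rm_$cs,
             kl = kl_divergence(wd$p, wd$q), js = js_divergence(wd$p, wd$q),
             stringsAsFactors = FALSE)
}
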