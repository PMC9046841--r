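#' Training configuration
#'
#' Gathers every knob of the unsupervised optimization: batch geometry,
#' neighbor count, loss balance, transform family, architecture configs, and
#' the single seed that fans out to parameter initialization, shuffling, and
#' transform sampling through independent derived streams.
#'
#' @param batch_size mini-batch size B (>= 4; the pairwise losses need at
#'   least two pairs to be informative).
#' @param K neighbor count for the per-batch graph (`K < batch_size`).
#' @param epochs passes over the training set.
#' @param optimizer_name `"adam"` (default) or `"sgd"`. The loss surface
#'   couples a very stiff quadratic term (graph-center, quadratic in the GCN
#'   weights) with much flatter encoder directions, so the per-coordinate
#'   step normalization of Adam is the dependable choice; plain SGD with
#'   momentum is provided for experimentation and needs a much smaller
#'   learning rate.
#' @param learning_rate step size (Adam default 0.003).
#' @param momentum SGD momentum (ignored by Adam, which uses 0.9/0.999).
#' @param weight_decay decoupled L2 shrinkage applied in the update. The
#'   batch-standardized heads make the objective invariant to the overall
#'   scale of many parameter blocks and bare updates drift along those
#'   scale-free directions; a small decay pins the parameter norm.
#' @param weights a [loss_weights()] (alpha, beta, margin).
#' @param lambda shared-neighbor threshold for the pseudo-label estimator;
#'   default `floor(K / 2)`.
#' @param transform a [transform_spec()] for the invariance view.
#' @param seed master seed.
#' @param encoder an [encoder_config()].
#' @param gcn a [gcn_config()].
#' @param rebuild_graph_transformed rebuild the adjacency from the transformed
#'   view's features instead of reusing the original view's graph (default
#'   `FALSE`: the invariance loss compares rows of the two views, which calls
#'   for one shared propagation structure).
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 16,
                         K = 5,
                         epochs = 10,
                         optimizer_name = c("adam", "sgd"),
                         learning_rate = 0.003,
                         momentum = 0.9,
                         weight_decay = 1e-3,
                         weights = loss_weights(),
                         lambda = NULL,
                         transform = transform_spec(),
                         seed = 0,
                         encoder = encoder_config(),
                         gcn = gcn_config(),
                         rebuild_graph_transformed = FALSE) {
  if (batch_size < 4) stop("batch_size must be >= 4")
  if (K >= batch_size) stop("K must be < batch_size")
  if (K < 1) stop("K must be >= 1")
  if (is.null(lambda)) lambda <- floor(K / 2)
  stopifnot(inherits(weights, "loss_weights"),
            inherits(transform, "transform_spec"),
            inherits(encoder, "encoder_config"),
            inherits(gcn, "gcn_config"))
  if (weight_decay < 0) stop("weight_decay must be non-negative")
  optimizer_name <- match.arg(optimizer_name)
  structure(list(batch_size = as.integer(batch_size), K = as.integer(K),
                 epochs = as.integer(epochs),
                 optimizer_name = optimizer_name,
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay,
                 weights = weights, lambda = lambda, transform = transform,
                 seed = as.integer(seed), encoder = encoder, gcn = gcn,
                 rebuild_graph_transformed = isTRUE(rebuild_graph_transformed)),
            class = "train_config")
}

zeros_like <- function(p) {
  if (is.null(p)) return(NULL)
  if (is.list(p)) return(lapply(p, zeros_like))
  out <- p
  out[] <- 0
  out
}

# elementwise binary map over two identically shaped nested parameter lists
param_map2 <- function(f, a, b) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) return(mapply(param_map2, a, b,
                                MoreArgs = list(f = f), SIMPLIFY = FALSE))
  f(a, b)
}

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(flat, skeleton) {
  pos <- 0L
  walk <- function(s) {
    if (is.null(s)) return(NULL)
    if (is.list(s)) return(lapply(s, walk))
    n <- length(s)
    v <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out <- s
    out[] <- v
    out
  }
  res <- walk(skeleton)
  if (pos != length(flat)) stop("parameter vector length mismatch")
  res
}

#' Initialize a training state
#'
#' Randomly initializes the encoder and GCN parameters and the optimizer
#' state; records the derived RNG streams so training is bit-reproducible and
#' resumable.
#'
#' @param config a [train_config()].
#' @return object of class `training_state`.
#' @export
init_training_state <- function(config) {
  stopifnot(inherits(config, "train_config"))
  master <- rng_stream(config$seed)
  init_rng <- rng_spawn(master, 1L)
  shuffle_rng <- rng_spawn(master, 2L)
  transform_rng <- rng_spawn(master, 3L)
  encoder <- encoder_init(config$encoder, init_rng)
  gcn <- gcn_init(config$encoder$feature_dim, config$gcn, init_rng)
  structure(list(
    encoder = encoder,
    gcn = gcn,
    opt = list(enc_m = zeros_like(encoder$params),
               enc_v = zeros_like(encoder$params),
               gcn_m = zeros_like(gcn$W),
               gcn_v = zeros_like(gcn$W)),
    epoch = 0L,
    step = 0L,
    rng_shuffle = rng_state(shuffle_rng),
    rng_transform = rng_state(transform_rng),
    history = data.frame(step = integer(), pc = numeric(), gc = numeric(),
                         ti = numeric(), total = numeric()),
    config = config
  ), class = "training_state")
}

# Forward + backward through both views with the graph, labels, and both
# batches held fixed. Returns the loss report and gradients for all
# parameters (encoder gradients accumulate over the two views, which share
# weights).
loss_forward_backward <- function(encoder, gcn, x, xp, Ahat, Ahat_p, A_loss,
                                  labels, weights, want_grads = TRUE) {
  fe <- encoder_forward(x, encoder, want_cache = want_grads)
  fz <- gcn_forward(fe$features, Ahat, gcn, normalized = TRUE,
                    want_cache = want_grads)
  fep <- encoder_forward(xp, encoder, want_cache = want_grads)
  fzp <- gcn_forward(fep$features, Ahat_p, gcn, normalized = TRUE,
                     want_cache = want_grads)
  Z <- fz$Z
  Zp <- fzp$Z

  gc_val <- 0.5 * sum(A_loss * pairwise_sqdist(Z))
  pc <- pc_loss_impl(Z, labels$l, weights$margin, want_grad = want_grads)
  ti <- ti_loss_impl(Z, Zp, want_grad = want_grads)
  report <- total_loss(pc$loss, gc_val, ti$loss, weights)
  if (!want_grads) return(list(report = report))

  dZ <- pc$grad + weights$alpha * graph_center_grad(Z, A_loss) +
    weights$beta * ti$grad_Z
  dZp <- weights$beta * ti$grad_Zp

  gb <- gcn_backward(dZ, fz$cache, gcn)
  gbp <- gcn_backward(dZp, fzp$cache, gcn)
  d_gcn <- param_map2(`+`, gb$dW, gbp$dW)
  g_enc <- encoder_backward(gb$dX, fe, encoder)
  g_enc_p <- encoder_backward(gbp$dX, fep, encoder)
  d_enc <- param_map2(`+`, g_enc, g_enc_p)

  list(report = report, grads = list(enc = d_enc, gcn = d_gcn))
}

#' Freeze one training step into a differentiable objective
#'
#' Computes the batch's transformed view, adjacency, normalized propagation
#' matrix, and pseudo-labels from the state's current parameters, then
#' returns closures evaluating the total loss (and its analytic gradient) as
#' a function of the flattened parameter vector with those discrete
#' quantities held fixed — exactly the quantity whose gradient the optimizer
#' follows, and the natural target for finite-difference verification.
#'
#' @param batch_images list of images, length `config$batch_size`.
#' @param state a `training_state`.
#' @param config a [train_config()].
#' @return list with `theta` (current flattened parameters), `value(theta)`,
#'   `value_and_grad(theta)`, the frozen `labels`/`adjacency`, and the
#'   advanced transform-RNG state.
#' @export
prepare_step_objective <- function(batch_images, state, config = state$config) {
  trng <- rng_restore(state$rng_transform)
  xp_list <- lapply(batch_images, apply_transform,
                    spec = config$transform, rng = trng)
  x <- images_to_tensor(batch_images)
  xp <- images_to_tensor(xp_list)

  f0 <- encoder_forward(x, state$encoder)$features
  adj <- build_knn_adjacency(f0, config$K)
  Ahat <- propagation_matrix(adj, state$gcn$config)
  labels <- estimate_pairwise_labels(adj, config$lambda)
  A_loss <- loss_adjacency(adj, nrow(f0))
  if (config$rebuild_graph_transformed) {
    fp0 <- encoder_forward(xp, state$encoder)$features
    Ahat_p <- propagation_matrix(build_knn_adjacency(fp0, config$K),
                                 state$gcn$config)
  } else {
    Ahat_p <- Ahat
  }

  skeleton <- list(enc = state$encoder$params, gcn = state$gcn$W)
  base_enc <- state$encoder
  base_gcn <- state$gcn
  with_theta <- function(theta) {
    p <- unflatten_params(theta, skeleton)
    enc <- base_enc
    enc$params <- p$enc
    gcn <- base_gcn
    gcn$W <- p$gcn
    list(enc = enc, gcn = gcn)
  }
  list(
    theta = flatten_params(skeleton),
    skeleton = skeleton,
    adjacency = adj,
    labels = labels,
    value = function(theta) {
      m <- with_theta(theta)
      loss_forward_backward(m$enc, m$gcn, x, xp, Ahat, Ahat_p, A_loss,
                            labels, config$weights,
                            want_grads = FALSE)$report$total
    },
    value_and_grad = function(theta) {
      m <- with_theta(theta)
      r <- loss_forward_backward(m$enc, m$gcn, x, xp, Ahat, Ahat_p, A_loss,
                                 labels, config$weights, want_grads = TRUE)
      list(loss = r$report$total, report = r$report,
           grad = flatten_params(list(enc = r$grads$enc, gcn = r$grads$gcn)),
           grads = r$grads)
    },
    rng_transform_after = rng_state(trng)
  )
}

#' One optimization step
#'
#' Encodes the batch, builds the KNN graph and pseudo-labels from the current
#' features, propagates both the original and the transformed view through
#' the GCN (sharing the original view's graph), assembles the combined loss,
#' and applies one SGD-with-momentum update to all encoder and GCN
#' parameters. The returned report is the pre-update loss.
#'
#' @param batch_images list of images of length `config$batch_size`.
#' @param state a `training_state`.
#' @param config a [train_config()]; defaults to the state's own.
#' @return list with `state` (updated) and `report` (a `loss_report`).
#' @export
train_step <- function(batch_images, state, config = state$config) {
  stopifnot(inherits(state, "training_state"))
  if (length(batch_images) != config$batch_size) {
    stop(sprintf("batch size %d != configured B = %d",
                 length(batch_images), config$batch_size))
  }
  obj <- prepare_step_objective(batch_images, state, config)
  r <- obj$value_and_grad(obj$theta)

  t_step <- state$step + 1L
  if (config$optimizer_name == "adam") {
    b1 <- 0.9
    b2 <- 0.999
    eps <- 1e-8
    lr <- config$learning_rate
    wd <- config$weight_decay
    for (grp in c("enc", "gcn")) {
      g <- if (grp == "enc") r$grads$enc else r$grads$gcn
      p <- if (grp == "enc") state$encoder$params else state$gcn$W
      m <- param_map2(function(m, g) b1 * m + (1 - b1) * g,
                      state$opt[[paste0(grp, "_m")]], g)
      v <- param_map2(function(v, g) b2 * v + (1 - b2) * g^2,
                      state$opt[[paste0(grp, "_v")]], g)
      mhat_scale <- 1 / (1 - b1^t_step)
      vhat_scale <- 1 / (1 - b2^t_step)
      upd <- param_map2(function(m, v) {
        lr * (m * mhat_scale) / (sqrt(v * vhat_scale) + eps)
      }, m, v)
      p <- param_map2(function(p, u) p * (1 - lr * wd) - u, p, upd)
      state$opt[[paste0(grp, "_m")]] <- m
      state$opt[[paste0(grp, "_v")]] <- v
      if (grp == "enc") state$encoder$params <- p else state$gcn$W <- p
    }
  } else {
    lr <- config$learning_rate
    mom <- config$momentum
    wd <- config$weight_decay
    state$opt$enc_m <- param_map2(function(v, g) mom * v - lr * g,
                                  state$opt$enc_m,
                                  param_map2(function(g, p) g + wd * p,
                                             r$grads$enc, state$encoder$params))
    state$opt$gcn_m <- param_map2(function(v, g) mom * v - lr * g,
                                  state$opt$gcn_m,
                                  param_map2(function(g, p) g + wd * p,
                                             r$grads$gcn, state$gcn$W))
    state$encoder$params <- param_map2(`+`, state$encoder$params,
                                       state$opt$enc_m)
    state$gcn$W <- param_map2(`+`, state$gcn$W, state$opt$gcn_m)
  }

  state$rng_transform <- obj$rng_transform_after
  state$step <- t_step
  state$history <- rbind(state$history,
                         data.frame(step = state$step, pc = r$report$pc,
                                    gc = r$report$gc, ti = r$report$ti,
                                    total = r$report$total))
  list(state = state, report = r$report)
}

#' Fit the model on an unlabeled image collection
#'
#' Iterates epochs of shuffled mini-batches of [train_step()]. The interface
#' accepts images only — ground-truth grades never enter any training code
#' path. The final partial batch of each epoch is dropped (the per-batch
#' graph and pairwise normalizers assume a fixed B).
#'
#' @param images list of H x W x 3 arrays, or a `graded_image_set` (only its
#'   `$images` element is used).
#' @param config a [train_config()].
#' @param out_dir optional directory for `checkpoint.bin`, `loss_trace.tsv`,
#'   and `config_resolved.yaml`.
#' @param verbose print per-epoch mean losses.
#' @return the final `training_state`.
#' @export
fit <- function(images, config, out_dir = NULL, verbose = FALSE) {
  if (inherits(images, "graded_image_set")) images <- images$images
  stopifnot(is.list(images))
  n <- length(images)
  if (n < config$batch_size) {
    stop(sprintf("insufficient data: %d images < one batch of %d",
                 n, config$batch_size))
  }
  state <- init_training_state(config)
  n_batches <- n %/% config$batch_size
  for (epoch in seq_len(config$epochs)) {
    srng <- rng_restore(state$rng_shuffle)
    ord <- rng_sample(srng, n, n)
    state$rng_shuffle <- rng_state(srng)
    for (bi in seq_len(n_batches)) {
      idx <- ord[((bi - 1) * config$batch_size + 1):(bi * config$batch_size)]
      st <- train_step(images[idx], state, config)
      state <- st$state
    }
    state$epoch <- epoch
    if (verbose) {
      tail_rows <- utils::tail(state$history, n_batches)
      message(sprintf("epoch %d: total %.4f (pc %.4f gc %.4f ti %.4f)",
                      epoch, mean(tail_rows$total), mean(tail_rows$pc),
                      mean(tail_rows$gc), mean(tail_rows$ti)))
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(state, file.path(out_dir, "checkpoint.bin"))
    utils::write.table(state$history, file.path(out_dir, "loss_trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(config_as_list(config),
                     file.path(out_dir, "config_resolved.yaml"))
  }
  state
}

#' Save / load a training checkpoint
#'
#' The checkpoint holds the encoder parameters, GCN weights, optimizer
#' velocities, RNG stream states, loss history, and the resolved config, so
#' `save -> load -> train_step` reproduces the uninterrupted trajectory
#' bit-for-bit, and eval-mode encoding round-trips bit-stably.
#'
#' @param state a `training_state`.
#' @param path file path.
#' @return `load_checkpoint` returns the restored `training_state`.
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "training_state"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  if (!inherits(state, "training_state")) stop("not a training checkpoint: ", path)
  state
}

# plain-list view of a config for YAML round-tripping
config_as_list <- function(config) {
  list(
    batch_size = config$batch_size, K = config$K, epochs = config$epochs,
    optimizer_name = config$optimizer_name,
    learning_rate = config$learning_rate, momentum = config$momentum,
    weight_decay = config$weight_decay,
    alpha = config$weights$alpha, beta = config$weights$beta,
    margin = config$weights$margin, lambda = config$lambda,
    seed = config$seed,
    transform = list(family = config$transform$family,
                     rotation_range = config$transform$rotation_range,
                     hflip_prob = config$transform$hflip_prob),
    encoder = list(architecture = config$encoder$architecture,
                   feature_dim = config$encoder$feature_dim,
                   input_filter = config$encoder$input_filter,
                   filter_sigma = config$encoder$filter_sigma,
                   conv1_init = config$encoder$conv1_init,
                   standardize_input = config$encoder$standardize_input,
                   batch_standardize_features = config$encoder$batch_standardize_features,
                   normalize_features = config$encoder$normalize_features),
    gcn = list(n_layers = config$gcn$n_layers,
               add_self_loops = config$gcn$add_self_loops,
               final_activation = config$gcn$final_activation,
               standardize_output = config$gcn$standardize_output),
    rebuild_graph_transformed = config$rebuild_graph_transformed
  )
}

config_from_list <- function(lst) {
  lst <- lst %||% list()
  tr <- lst$transform %||% list()
  en <- lst$encoder %||% list()
  gc_ <- lst$gcn %||% list()
  train_config(
    batch_size = lst$batch_size %||% 16,
    K = lst$K %||% 5,
    epochs = lst$epochs %||% 10,
    optimizer_name = lst$optimizer_name %||% "adam",
    learning_rate = lst$learning_rate %||% 0.003,
    momentum = lst$momentum %||% 0.9,
    weight_decay = lst$weight_decay %||% 1e-3,
    weights = loss_weights(alpha = lst$alpha %||% 0.1,
                           beta = lst$beta %||% 0.1,
                           margin = lst$margin %||% 1),
    lambda = lst$lambda,
    transform = transform_spec(
      family = tr$family %||% "rotation",
      rotation_range = tr$rotation_range %||% c(-30, 30),
      hflip_prob = tr$hflip_prob %||% 0.5),
    seed = lst$seed %||% 0,
    encoder = encoder_config(
      architecture = en$architecture %||% "small_conv",
      feature_dim = en$feature_dim %||% 16,
      input_filter = en$input_filter %||% "center_surround",
      filter_sigma = en$filter_sigma %||% 2.5,
      conv1_init = en$conv1_init %||% "blob",
      standardize_input = en$standardize_input %||% TRUE,
      batch_standardize_features = en$batch_standardize_features %||% TRUE,
      normalize_features = en$normalize_features %||% FALSE),
    gcn = gcn_config(
      n_layers = gc_$n_layers %||% 1,
      add_self_loops = gc_$add_self_loops %||% TRUE,
      final_activation = gc_$final_activation %||% FALSE,
      standardize_output = gc_$standardize_output %||% TRUE),
    rebuild_graph_transformed = lst$rebuild_graph_transformed %||% FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
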