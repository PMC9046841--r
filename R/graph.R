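#' Build the K-nearest-neighbor adjacency of a feature batch
#'
#' Each sample is connected to its K nearest neighbors in Euclidean feature
#' space (self excluded, distance ties broken by lowest index). The directed
#' selection is symmetrized by logical OR — an edge exists if either endpoint
#' selects the other — since the symmetric degree normalization used by the
#' graph convolution presumes a symmetric adjacency.
#'
#' @param features B x d numeric matrix, or the result of [encode_batch()].
#' @param K neighbor count, `1 <= K <= B - 1`.
#' @return object of class `knn_adjacency`: list with `A` (symmetrized 0/1
#'   matrix, zero diagonal), `A_directed`, `neighbor_sets` (list of K indices
#'   per sample), and `K`.
#' @export
build_knn_adjacency <- function(features, K) {
  if (is.list(features) && !is.null(features$features)) {
    features <- features$features
  }
  features <- as.matrix(features)
  B <- nrow(features)
  if (!all(is.finite(features))) stop("invalid input: non-finite features")
  if (K < 1 || K >= B) {
    stop(sprintf("invalid K = %d for batch size B = %d (need 1 <= K <= B-1)", K, B))
  }
  D <- as.matrix(stats::dist(features))
  diag(D) <- Inf
  neighbor_sets <- vector("list", B)
  A_dir <- matrix(0L, B, B)
  for (k in seq_len(B)) {
    nb <- order(D[k, ])[seq_len(K)]   # stable order: ties go to lowest index
    neighbor_sets[[k]] <- as.integer(nb)
    A_dir[k, nb] <- 1L
  }
  A <- 1L * ((A_dir + t(A_dir)) > 0)
  diag(A) <- 0L
  structure(list(A = A, A_directed = A_dir,
                 neighbor_sets = neighbor_sets, K = as.integer(K)),
            class = "knn_adjacency")
}

#' Symmetric degree normalization of an adjacency matrix
#'
#' Returns `D^{-1/2} A D^{-1/2}` with `D = diag(rowSums(A))`. Self-loop
#' policy is the caller's: pass `A + I` to include them.
#'
#' @param A square non-negative matrix with strictly positive row sums.
#' @return normalized matrix of the same shape.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  deg <- rowSums(A)
  if (any(deg <= 0)) {
    stop("degenerate graph: zero-degree node(s) ",
         paste(which(deg <= 0), collapse = ","),
         "; enable self-loops before normalizing")
  }
  dh <- 1 / sqrt(deg)
  A * outer(dh, dh)
}

#' Graph-convolution configuration
#'
#' The network has `n_layers` propagation layers, each computing
#' `X <- act(Ahat X W)` with `Ahat` the degree-normalized adjacency
#' (self-loops added first when `add_self_loops`). Hidden layers use ReLU;
#' by default the last layer is linear so the embedding occupies the full
#' space that the Euclidean losses measure.
#'
#' @param n_layers number of propagation layers (>= 1).
#' @param layer_dims output dimension per layer; defaults to the input
#'   feature dimension throughout (resolved at initialization).
#' @param add_self_loops add `I` to the adjacency before normalization
#'   (default `TRUE`; prevents zero-degree failure).
#' @param final_activation apply ReLU after the last layer too (default
#'   `FALSE`).
#' @param standardize_output if `TRUE` (default), z-score each output
#'   dimension of Z across the batch (batch normalization without affine
#'   parameters). This pins the embedding's per-dimension variance, so the
#'   attractive training terms (graph-center, same-class pairs, transform
#'   invariance) cannot be satisfied by shrinking the graph weights toward
#'   zero — they must rearrange the embedding instead. Disable to obtain the
#'   raw propagation output.
#' @return object of class `gcn_config`.
#' @export
gcn_config <- function(n_layers = 1, layer_dims = NULL,
                       add_self_loops = TRUE, final_activation = FALSE,
                       standardize_output = TRUE) {
  if (n_layers < 1) stop("n_layers must be >= 1")
  structure(list(n_layers = as.integer(n_layers),
                 layer_dims = layer_dims,
                 add_self_loops = isTRUE(add_self_loops),
                 final_activation = isTRUE(final_activation),
                 standardize_output = isTRUE(standardize_output)),
            class = "gcn_config")
}

#' Initialize graph-convolution weights
#'
#' @param d_in input feature dimension (the encoder's `feature_dim`).
#' @param config a [gcn_config()].
#' @param rng a [rng_stream()].
#' @return object of class `dgcn_gcn` with resolved `dims` and weight list `W`.
#' @export
gcn_init <- function(d_in, config, rng) {
  stopifnot(inherits(config, "gcn_config"))
  dims <- config$layer_dims
  if (is.null(dims)) dims <- rep(as.integer(d_in), config$n_layers)
  if (length(dims) != config$n_layers) {
    stop("layer_dims must have one entry per layer")
  }
  all_dims <- c(as.integer(d_in), as.integer(dims))
  W <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    W[[l]] <- matrix(rng_rnorm(rng, all_dims[l] * all_dims[l + 1], 0,
                               sqrt(1 / all_dims[l])),
                     all_dims[l], all_dims[l + 1])
  }
  structure(list(config = config, dims = all_dims, W = W), class = "dgcn_gcn")
}

# Resolve the propagation matrix for an adjacency under the self-loop policy.
propagation_matrix <- function(adj, config) {
  A <- if (inherits(adj, "knn_adjacency")) adj$A else as.matrix(adj)
  if (config$add_self_loops) A <- A + diag(nrow(A))
  normalize_adjacency(A)
}

#' Propagate a feature batch through the graph convolution
#'
#' Computes `X^(l) = act(Ahat X^(l-1) W^(l))` layer by layer, starting from
#' the encoder features, and returns the last layer's output Z.
#'
#' @param features B x d_in matrix (or [encode_batch()] result).
#' @param adj a [build_knn_adjacency()] result, a raw adjacency matrix, or an
#'   already-normalized propagation matrix (`normalized = TRUE`).
#' @param gcn a [gcn_init()] result.
#' @param normalized set `TRUE` when `adj` is already the normalized
#'   propagation matrix.
#' @param want_cache keep intermediate activations for the backward pass.
#' @return list with `Z` (B x d_out matrix) and optionally `cache`.
#' @export
gcn_forward <- function(features, adj, gcn, normalized = FALSE,
                        want_cache = FALSE) {
  if (is.list(features) && !is.null(features$features)) {
    features <- features$features
  }
  X <- as.matrix(features)
  stopifnot(inherits(gcn, "dgcn_gcn"))
  if (ncol(X) != gcn$dims[1]) {
    stop(sprintf("configuration error: feature dim %d != GCN input dim %d",
                 ncol(X), gcn$dims[1]))
  }
  Ahat <- if (normalized) as.matrix(adj) else propagation_matrix(adj, gcn$config)
  if (nrow(Ahat) != nrow(X)) {
    stop("configuration error: adjacency size does not match batch size")
  }
  L <- gcn$config$n_layers
  pre_list <- vector("list", L)
  x_list <- vector("list", L + 1)
  x_list[[1]] <- X
  for (l in seq_len(L)) {
    pre <- Ahat %*% x_list[[l]] %*% gcn$W[[l]]
    act <- l < L || gcn$config$final_activation
    pre_list[[l]] <- pre
    x_list[[l + 1]] <- if (act) pmax(pre, 0) else pre
  }
  Z <- x_list[[L + 1]]
  bn_cache <- NULL
  if (gcn$config$standardize_output) {
    bn <- batchstd_forward(Z)
    Z <- bn$out
    bn_cache <- bn$cache
  }
  if (!all(is.finite(Z))) stop("graph convolution produced non-finite values")
  if (want_cache) {
    list(Z = Z, cache = list(Ahat = Ahat, x_list = x_list,
                             pre_list = pre_list, bn = bn_cache))
  } else {
    list(Z = Z)
  }
}

# Backward pass through the graph convolution: given dL/dZ, returns dL/dX
# (to feed the encoder) and dL/dW per layer. Ahat is symmetric, so
# t(Ahat) %*% . = Ahat %*% .
gcn_backward <- function(dZ, cache, gcn) {
  L <- gcn$config$n_layers
  dW <- vector("list", L)
  if (gcn$config$standardize_output) dZ <- batchstd_backward(dZ, cache$bn)
  dX <- dZ
  for (l in rev(seq_len(L))) {
    act <- l < L || gcn$config$final_activation
    dpre <- if (act) dX * (cache$pre_list[[l]] > 0) else dX
    AX <- cache$Ahat %*% cache$x_list[[l]]
    dW[[l]] <- crossprod(AX, dpre)
    dX <- crossprod(cache$Ahat, tcrossprod(dpre, gcn$W[[l]]))
  }
  list(dX = dX, dW = dW)
}
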