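# The three unsupervised training objectives and the shared-neighbor
# pseudo-label estimator. Each loss has a companion *_grad() returning the
# analytic gradient with respect to the embedding rows; adjacency and
# pseudo-labels are discrete selections, recomputed each batch and treated
# as constants in the backward pass.

pairwise_sqdist <- function(Z) {
  G <- rowSums(Z^2)
  D2 <- outer(G, G, "+") - 2 * tcrossprod(Z)
  pmax(D2, 0)
}

#' Graph-center loss
#'
#' `0.5 * sum_kj A_kj ||Z_j - Z_k||^2`: pulls graph-connected embeddings
#' together. Uses the symmetrized zero-diagonal adjacency (self-loops are a
#' propagation device, not a loss term).
#'
#' @param Z B x d embedding matrix (or a [gcn_forward()] result).
#' @param adj a [build_knn_adjacency()] result or a 0/1 matrix.
#' @return non-negative scalar.
#' @export
graph_center_loss <- function(Z, adj) {
  Z <- as_embedding(Z)
  A <- loss_adjacency(adj, nrow(Z))
  0.5 * sum(A * pairwise_sqdist(Z))
}

graph_center_grad <- function(Z, A) {
  2 * (rowSums(A) * Z - A %*% Z)
}

as_embedding <- function(Z) {
  if (is.list(Z) && !is.null(Z$Z)) Z <- Z$Z
  as.matrix(Z)
}

loss_adjacency <- function(adj, B) {
  A <- if (inherits(adj, "knn_adjacency")) adj$A else as.matrix(adj)
  if (nrow(A) != B || ncol(A) != B) {
    stop("invalid input: adjacency does not match embedding rows")
  }
  diag(A) <- 0
  A
}

#' Estimate pairwise same-class pseudo-labels from shared neighbors
#'
#' Two samples whose K-nearest-neighbor sets overlap in strictly more than
#' `lambda` members are declared same-class (`l = 1`); all other pairs are
#' declared different-class (`l = 0`). The intersection excludes the samples
#' themselves, and the diagonal is undefined (`NA`) — pairs `k = j` never
#' enter a loss.
#'
#' @param neighbor_sets list of neighbor index vectors (one per sample), or a
#'   [build_knn_adjacency()] result.
#' @param lambda shared-neighbor threshold, `0 <= lambda <= K`.
#' @return object of class `pairwise_labels`: list with `l` (B x B 0/1 matrix,
#'   `NA` diagonal), `shared` (intersection sizes), and `lambda`.
#' @export
estimate_pairwise_labels <- function(neighbor_sets, lambda) {
  if (inherits(neighbor_sets, "knn_adjacency")) {
    neighbor_sets <- neighbor_sets$neighbor_sets
  }
  B <- length(neighbor_sets)
  K <- length(neighbor_sets[[1]])
  if (lambda < 0) stop("lambda must be non-negative")
  if (lambda > K) {
    warning(sprintf("lambda = %s exceeds K = %d: every pair labeled 0", lambda, K))
  }
  maxi <- max(B, unlist(neighbor_sets))
  M <- matrix(0L, B, maxi)
  for (k in seq_len(B)) M[k, neighbor_sets[[k]]] <- 1L
  shared <- tcrossprod(M)
  l <- 1L * (shared > lambda)
  diag(l) <- NA_integer_
  structure(list(l = l, shared = shared, lambda = lambda),
            class = "pairwise_labels")
}

#' Pseudo-contrastive loss
#'
#' Margin contrastive loss over all unordered batch pairs, driven by the
#' estimated pairwise labels: same-class pairs pay their squared distance,
#' different-class pairs pay a squared hinge `max(margin - d, 0)^2`. The sum
#' is divided by `2 * N_pairs` where `N_pairs` is the number of unordered
#' pairs actually summed.
#'
#' @param Z B x d embedding matrix (or a [gcn_forward()] result).
#' @param labels a [estimate_pairwise_labels()] result or a 0/1 matrix with
#'   ignored diagonal.
#' @param margin positive margin m.
#' @return non-negative scalar.
#' @export
pseudo_contrastive_loss <- function(Z, labels, margin) {
  pc_loss_impl(as_embedding(Z), label_matrix(labels), margin)$loss
}

label_matrix <- function(labels) {
  l <- if (inherits(labels, "pairwise_labels")) labels$l else as.matrix(labels)
  l
}

pc_loss_impl <- function(Z, l, margin, want_grad = FALSE) {
  if (!is.numeric(margin) || margin <= 0) {
    stop("configuration error: margin must be > 0")
  }
  B <- nrow(Z)
  if (nrow(l) != B || ncol(l) != B) {
    stop("invalid input: label matrix does not match embedding rows")
  }
  D2 <- pairwise_sqdist(Z)
  D <- sqrt(D2)
  lnum <- l
  lnum[is.na(lnum)] <- 0
  hinge <- pmax(margin - D, 0)
  up <- upper.tri(D)
  n_pairs <- sum(up)
  terms <- lnum * D2 + (1 - lnum) * hinge^2
  loss <- sum(terms[up]) / (2 * n_pairs)
  if (!want_grad) return(list(loss = loss))
  # per-pair coefficient w_kj on (Z_k - Z_j); symmetric, zero diagonal
  Dsafe <- D
  Dsafe[Dsafe == 0] <- 1
  Wc <- lnum * 2 + (1 - lnum) * (-2 * hinge / Dsafe) * (D > 0)
  diag(Wc) <- 0
  grad <- (rowSums(Wc) * Z - Wc %*% Z) / (2 * n_pairs)
  list(loss = loss, grad = grad)
}

#' Transform-invariant loss
#'
#' Mean unsquared Euclidean distance between the embedding of each image and
#' the embedding of its randomly transformed copy:
#' `(1/B) * sum_k ||Z_k - Z'_k||`.
#'
#' @param Z,Z_transformed row-aligned B x d embedding matrices (row k of
#'   `Z_transformed` embeds the transformed copy of image k).
#' @return non-negative scalar.
#' @export
transform_invariant_loss <- function(Z, Z_transformed) {
  ti_loss_impl(as_embedding(Z), as_embedding(Z_transformed))$loss
}

ti_loss_impl <- function(Z, Zp, want_grad = FALSE) {
  if (nrow(Z) != nrow(Zp) || ncol(Z) != ncol(Zp)) {
    stop("invalid input: embeddings of the two views are not row-aligned")
  }
  B <- nrow(Z)
  diffs <- Z - Zp
  nrm <- sqrt(rowSums(diffs^2))
  loss <- mean(nrm)
  if (!want_grad) return(list(loss = loss))
  safe <- ifelse(nrm > 1e-12, nrm, 1)
  g <- diffs / safe / B
  g[nrm <= 1e-12, ] <- 0
  list(loss = loss, grad_Z = g, grad_Zp = -g)
}

#' Combine the three losses into the overall training objective
#'
#' `total = pc + alpha * gc + beta * ti`.
#'
#' @param pc,gc,ti finite component values.
#' @param weights a [loss_weights()] object.
#' @return object of class `loss_report` with fields `pc`, `gc`, `ti`,
#'   `total`.
#' @export
total_loss <- function(pc, gc, ti, weights) {
  stopifnot(inherits(weights, "loss_weights"))
  for (nm in c("pc", "gc", "ti")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("numeric error: loss component '", nm, "' is not a finite scalar")
    }
  }
  structure(list(pc = pc, gc = gc, ti = ti,
                 total = pc + weights$alpha * gc + weights$beta * ti),
            class = "loss_report")
}

#' Loss balance weights
#'
#' @param alpha weight on the graph-center term (>= 0).
#' @param beta weight on the transform-invariant term (>= 0).
#' @param margin contrastive margin m (> 0).
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 0.1, beta = 0.1, margin = 1) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be non-negative")
  if (margin <= 0) stop("configuration error: margin must be > 0")
  structure(list(alpha = alpha, beta = beta, margin = margin),
            class = "loss_weights")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("loss: total %.6g (pc %.6g, gc %.6g, ti %.6g)\n",
              x$total, x$pc, x$gc, x$ti))
  invisible(x)
}
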