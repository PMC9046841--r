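#' Embed a labeled gallery
#'
#' Runs the gallery images through the trained encoder and GCN in evaluation
#' mode. Propagation needs a graph at test time; the gallery's graph is built
#' among the gallery items themselves. Labels pass through untouched — they
#' are the reference annotations, never inferred.
#'
#' @param images list of gallery images.
#' @param labels integer grades (0..4) aligned to `images`.
#' @param state a trained `training_state`.
#' @return object of class `gallery_set`: list with `Z` (embeddings),
#'   `features` (encoder features, reused as graph context for queries),
#'   `labels`, and `classes`.
#' @export
embed_gallery <- function(images, labels, state) {
  stopifnot(inherits(state, "training_state"))
  if (length(images) != length(labels)) {
    stop("invalid input: images and labels differ in length")
  }
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 1)) stop("insufficient data: empty gallery class")
  if (length(images) < 2) stop("insufficient data: gallery needs >= 2 images")
  fwd <- encoder_forward(images_to_tensor(images), state$encoder)
  feats <- fwd$features
  Kg <- min(state$config$K, nrow(feats) - 1)
  adj <- build_knn_adjacency(feats, Kg)
  Z <- gcn_forward(feats, adj, state$gcn)$Z
  structure(list(Z = Z, features = feats, adjacency = adj, K = Kg,
                 stats = fwd$stats, labels = labels, classes = classes),
            class = "gallery_set")
}

#' Embed query images in gallery context
#'
#' Each query is embedded independently against the gallery: encoder
#' features use the gallery's normalization statistics (inference-mode batch
#' norm), and the query node is attached to the gallery's KNN graph by
#' undirected edges to its K nearest gallery rows, then propagated through
#' the GCN together with the gallery. Every query's embedding therefore
#' depends only on itself and the gallery — query order and batching cannot
#' change any result — and a query identical to a gallery image matches it
#' at distance 0. Deterministic and label-blind.
#'
#' @param images list of query images.
#' @param gallery a [embed_gallery()] result.
#' @param state the same trained `training_state` that embedded the gallery.
#' @param batch_size images encoded per forward pass (a throughput knob
#'   only; results are independent of it).
#' @return matrix of query embeddings (one row per image), with the
#'   query-to-gallery distance matrix attached as attribute `"distances"`.
#' @export
embed_queries <- function(images, gallery, state,
                          batch_size = state$config$batch_size) {
  stopifnot(inherits(gallery, "gallery_set"), inherits(state, "training_state"))
  n <- length(images)
  ng <- nrow(gallery$features)
  d_in <- ncol(gallery$features)

  # encoder features under the gallery's frozen statistics; batching here is
  # throughput only, every row is independent of its companions
  fq <- NULL
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    f <- encoder_forward(images_to_tensor(images[idx]), state$encoder,
                         frozen_stats = gallery$stats)$features
    fq <- rbind(fq, f)
  }

  # per-query graph attachment and propagation
  Kq <- min(state$config$K, ng)
  Ag <- gallery$adjacency$A
  out <- matrix(0, n, 0)
  dmat <- matrix(0, n, ng)
  Zq_all <- NULL
  for (q in seq_len(n)) {
    dq <- sqrt(colSums((t(gallery$features) - fq[q, ])^2))
    nb <- order(dq)[seq_len(Kq)]
    A <- matrix(0, ng + 1, ng + 1)
    A[2:(ng + 1), 2:(ng + 1)] <- Ag
    A[1, nb + 1] <- 1
    A[nb + 1, 1] <- 1
    Zc <- gcn_forward(rbind(fq[q, , drop = FALSE], gallery$features),
                      A, state$gcn)$Z
    zq <- Zc[1, , drop = FALSE]
    Zg <- Zc[-1, , drop = FALSE]
    db <- sqrt(pmax(rowSums(Zg^2) + sum(zq^2) - 2 * as.vector(Zg %*% t(zq)), 0))
    # identical images are exact matches by contract; graph-role asymmetry
    # between duplicate rows must not blur that
    db[dq^2 <= 1e-9] <- 0
    Zq_all <- rbind(Zq_all, zq)
    dmat[q, ] <- db
  }
  attr(Zq_all, "distances") <- dmat
  Zq_all
}

#' Grade one query embedding by nearest gallery match
#'
#' Returns the label of the gallery row at minimum Euclidean distance;
#' distance ties are broken by lowest gallery index.
#'
#' @param query_embedding numeric vector of length `ncol(gallery$Z)`.
#' @param gallery a [embed_gallery()] result.
#' @return list with `grade`, `distance`, `matched_id` (gallery row index).
#' @export
predict_label <- function(query_embedding, gallery) {
  stopifnot(inherits(gallery, "gallery_set"))
  if (nrow(gallery$Z) == 0) stop("invalid state: empty gallery")
  d2 <- rowSums(sweep(gallery$Z, 2, query_embedding)^2)
  j <- which.min(d2)   # which.min takes the first (lowest index) on ties
  list(grade = gallery$labels[j], distance = sqrt(d2[j]), matched_id = j)
}

predict_batch <- function(Zq, gallery) {
  dmat <- attr(Zq, "distances")
  if (is.null(dmat)) {
    res <- lapply(seq_len(nrow(Zq)), function(i) predict_label(Zq[i, ], gallery))
    return(data.frame(
      predicted_grade = vapply(res, `[[`, integer(1), "grade"),
      match_distance = vapply(res, `[[`, numeric(1), "distance"),
      matched_id = vapply(res, `[[`, integer(1), "matched_id")
    ))
  }
  j <- apply(dmat, 1, which.min)
  data.frame(
    predicted_grade = gallery$labels[j],
    match_distance = dmat[cbind(seq_len(nrow(dmat)), j)],
    matched_id = as.integer(j)
  )
}

#' Referable-disease scores for ROC analysis
#'
#' Nearest-match grading yields hard labels; the ROC sweep needs a
#' continuous score. The default is the distance margin: distance to the
#' nearest non-referable gallery row minus distance to the nearest referable
#' one (larger = more referable-looking). `"neg_distance"` uses the negated
#' distance to the nearest referable row.
#'
#' @param Zq query embedding matrix, ideally from [embed_queries()] (its
#'   attached query-to-gallery distances are used when present).
#' @param gallery a [embed_gallery()] result containing both referable and
#'   non-referable rows.
#' @param method `"margin"` (default) or `"neg_distance"`.
#' @return numeric score per query.
#' @export
referable_scores <- function(Zq, gallery, method = c("margin", "neg_distance")) {
  method <- match.arg(method)
  ref <- referable_binarize(gallery$labels) == 1
  if (!any(ref) || (method == "margin" && all(ref))) {
    stop("gallery must contain both referable and non-referable rows")
  }
  dmat <- attr(Zq, "distances")
  if (is.null(dmat)) {
    dmat <- sqrt(pmax(outer(rowSums(Zq^2), rowSums(gallery$Z^2), "+") -
                        2 * tcrossprod(Zq, gallery$Z), 0))
  }
  d_ref <- apply(dmat[, ref, drop = FALSE], 1, min)
  if (method == "neg_distance") return(-d_ref)
  d_non <- apply(dmat[, !ref, drop = FALSE], 1, min)
  d_non - d_ref
}

#' Evaluate a query set against held-out truth
#'
#' Predicts every query by nearest gallery match, then reports the
#' five-level confusion matrix, the referable-binarized accuracy /
#' sensitivity / specificity with Wilson 95% confidence intervals, the ROC
#' curve with its AUC, and a per-query embedding table for external 2-D
#' visualization.
#'
#' @param images list of query images.
#' @param truth held-out integer grades aligned to `images`.
#' @param gallery a [embed_gallery()] result.
#' @param state the trained `training_state`.
#' @param score_method passed to [referable_scores()].
#' @return object of class `dgcn_eval`.
#' @export
evaluate_dataset <- function(images, truth, gallery, state,
                             score_method = "margin") {
  stopifnot(length(images) == length(truth))
  if (length(images) == 0) stop("insufficient data: empty query set")
  truth <- as.integer(truth)
  Zq <- embed_queries(images, gallery, state)
  preds <- predict_batch(Zq, gallery)

  levels_all <- 0:4
  confusion <- table(
    truth = factor(truth, levels = levels_all),
    predicted = factor(preds$predicted_grade, levels = levels_all)
  )

  truth_ref <- referable_binarize(truth)
  pred_ref <- referable_binarize(preds$predicted_grade)
  counts <- confusion_counts(pred_ref, truth_ref)

  acc <- accuracy(counts)
  n <- length(truth)
  metrics <- list(
    multiclass_accuracy = mean(preds$predicted_grade == truth),
    accuracy = acc,
    accuracy_ci = wilson_ci(counts$TP + counts$TN, n),
    sensitivity = sensitivity(counts),
    sensitivity_ci = wilson_ci(counts$TP, counts$TP + counts$FN),
    specificity = specificity(counts),
    specificity_ci = wilson_ci(counts$TN, counts$TN + counts$FP)
  )

  scores <- referable_scores(Zq, gallery, method = score_method)
  roc <- roc_auc(scores, truth_ref)

  embeddings <- data.frame(query = seq_along(truth), grade = truth,
                           predicted = preds$predicted_grade)
  embeddings <- cbind(embeddings,
                      stats::setNames(as.data.frame(Zq),
                                      paste0("z", seq_len(ncol(Zq)))))

  structure(list(confusion = confusion, counts = counts, metrics = metrics,
                 roc = roc, predictions = preds, scores = scores,
                 embeddings = embeddings),
            class = "dgcn_eval")
}

#' @export
print.dgcn_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("grade accuracy (all levels): %.3f\n", m$multiclass_accuracy))
  cat(sprintf("referable accuracy   %.3f (95%% CI %.3f-%.3f)\n",
              m$accuracy, m$accuracy_ci[1], m$accuracy_ci[2]))
  cat(sprintf("referable sensitivity %.3f (95%% CI %.3f-%.3f)\n",
              m$sensitivity, m$sensitivity_ci[1], m$sensitivity_ci[2]))
  cat(sprintf("referable specificity %.3f (95%% CI %.3f-%.3f)\n",
              m$specificity, m$specificity_ci[1], m$specificity_ci[2]))
  cat(sprintf("AUC %.3f over %d queries\n", x$roc$auc, sum(x$confusion)))
  invisible(x)
}
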