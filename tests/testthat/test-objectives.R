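test_that("graph-center loss matches hand computations", {
  # identical rows: all pairwise differences vanish
  Z <- matrix(1, 4, 3)
  A <- matrix(1, 4, 4) - diag(4)
  expect_equal(graph_center_loss(Z, A), 0)
  # mutual edge between (0,0) and (3,4): 25 counted in both orders, halved
  Z2 <- rbind(c(0, 0), c(3, 4))
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(graph_center_loss(Z2, A2), 25)
  # empty graph: empty sum
  expect_equal(graph_center_loss(Z2, matrix(0, 2, 2)), 0)
})

test_that("pairwise label estimator implements the strict shared-neighbor rule", {
  sets <- list(c(1, 2, 3), c(1, 2, 3))
  expect_equal(estimate_pairwise_labels(sets, 2)$l[1, 2], 1L)
  sets <- list(c(1, 2, 3), c(4, 5, 6))
  expect_equal(estimate_pairwise_labels(sets, 0)$l[1, 2], 0L)
  sets <- list(c(1, 2, 3), c(2, 3, 4))
  expect_equal(estimate_pairwise_labels(sets, 1)$l[1, 2], 1L)  # |int| = 2 > 1
  expect_equal(estimate_pairwise_labels(sets, 2)$l[1, 2], 0L)  # 2 not > 2
})

test_that("labels are symmetric with an undefined diagonal", {
  rng <- rng_stream(5)
  sets <- lapply(1:8, function(k) rng_sample(rng, setdiff(1:8, k), 3))
  lab <- estimate_pairwise_labels(sets, 1)
  expect_identical(lab$l[lower.tri(lab$l)], t(lab$l)[lower.tri(lab$l)])
  expect_true(all(is.na(diag(lab$l))))
})

test_that("lambda above K warns and labels every pair different-class", {
  sets <- list(c(2, 3), c(1, 3), c(1, 2))
  expect_warning(lab <- estimate_pairwise_labels(sets, 5), "exceeds K")
  expect_true(all(lab$l[upper.tri(lab$l)] == 0))
})

test_that("adding a common neighbor never flips a positive label off", {
  rng <- rng_stream(6)
  for (rep in 1:25) {
    a <- rng_sample(rng, 20, 4)
    b <- rng_sample(rng, 20, 4)
    lam <- rep %% 4
    before <- estimate_pairwise_labels(list(a, b), lam)$l[1, 2]
    newel <- 21 + rep
    after <- estimate_pairwise_labels(list(c(a, newel), c(b, newel)), lam)$l[1, 2]
    expect_gte(after, before)
  }
})

test_that("pseudo-contrastive loss matches hand computations", {
  # one pair at distance 0 with same-class label
  Z <- matrix(0, 2, 2)
  expect_equal(pseudo_contrastive_loss(Z, matrix(1, 2, 2), margin = 2), 0)
  # distance beyond the margin zeroes the hinge
  Z <- rbind(c(0, 0), c(3, 0))
  expect_equal(pseudo_contrastive_loss(Z, matrix(0, 2, 2), margin = 2), 0)
  # hinge: (1/2) * (2 - 1)^2 = 0.5
  Z <- rbind(c(0, 0), c(1, 0))
  expect_equal(pseudo_contrastive_loss(Z, matrix(0, 2, 2), margin = 2), 0.5)
  # same-class at distance 2: (1/2) * 4 = 2
  Z <- rbind(c(0, 0), c(2, 0))
  expect_equal(pseudo_contrastive_loss(Z, matrix(1, 2, 2), margin = 2), 2)
})

test_that("non-positive margins are configuration errors", {
  Z <- matrix(rnorm(8), 4, 2)
  expect_error(pseudo_contrastive_loss(Z, matrix(0, 4, 4), margin = 0),
               "configuration error")
  expect_error(loss_weights(margin = -1), "configuration error")
})

test_that("transform-invariant loss is the mean unsquared row distance", {
  Z <- matrix(rnorm(10), 5, 2)
  expect_equal(transform_invariant_loss(Z, Z), 0)
  Z1 <- rbind(c(0, 0), c(0, 0))
  Z2 <- rbind(c(3, 0), c(0, 1))   # row norms 3 and 1
  expect_equal(transform_invariant_loss(Z1, Z2), 2)
  expect_equal(transform_invariant_loss(matrix(0, 1, 1), matrix(5, 1, 1)), 5)
  expect_error(transform_invariant_loss(matrix(0, 2, 2), matrix(0, 3, 2)),
               "row-aligned")
})

test_that("total loss combines components linearly", {
  expect_equal(total_loss(0.7, 9, 4, loss_weights(alpha = 0, beta = 0))$total, 0.7)
  r <- total_loss(0.5, 25, 2, loss_weights(alpha = 1, beta = 1))
  expect_equal(r$total, 27.5)
  expect_equal(total_loss(0, 0, 0, loss_weights())$total, 0)
  expect_error(total_loss(NaN, 0, 0, loss_weights()), "numeric error.*pc")
})

test_that("losses are invariant under joint batch permutation", {
  rng <- rng_stream(9)
  Z <- matrix(rng_rnorm(rng, 8 * 3), 8, 3)
  Zp <- matrix(rng_rnorm(rng, 8 * 3), 8, 3)
  adj <- build_knn_adjacency(Z, 3)
  lab <- estimate_pairwise_labels(adj, 1)
  perm <- c(3, 8, 1, 5, 2, 7, 4, 6)
  Ap <- adj$A[perm, perm]
  lp <- lab$l[perm, perm]
  expect_equal(graph_center_loss(Z[perm, ], Ap), graph_center_loss(Z, adj$A))
  expect_equal(pseudo_contrastive_loss(Z[perm, ], lp, 1),
               pseudo_contrastive_loss(Z, lab$l, 1))
  expect_equal(transform_invariant_loss(Z[perm, ], Zp[perm, ]),
               transform_invariant_loss(Z, Zp))
})

test_that("losses are invariant under rigid translation of the embedding", {
  rng <- rng_stream(10)
  Z <- matrix(rng_rnorm(rng, 6 * 4), 6, 4)
  Zp <- matrix(rng_rnorm(rng, 6 * 4), 6, 4)
  adj <- build_knn_adjacency(Z, 2)
  lab <- estimate_pairwise_labels(adj, 1)
  shift <- matrix(rep(c(3, -1, 2, 0.5), each = 6), 6, 4)
  expect_equal(graph_center_loss(Z + shift, adj$A), graph_center_loss(Z, adj$A))
  expect_equal(pseudo_contrastive_loss(Z + shift, lab$l, 1),
               pseudo_contrastive_loss(Z, lab$l, 1))
  expect_equal(transform_invariant_loss(Z + shift, Zp + shift),
               transform_invariant_loss(Z, Zp))
})

test_that("analytic loss gradients match central differences on raw embeddings", {
  rng <- rng_stream(11)
  Z <- matrix(rng_rnorm(rng, 6 * 3), 6, 3)
  Zp <- matrix(rng_rnorm(rng, 6 * 3), 6, 3)
  adj <- build_knn_adjacency(Z, 2)
  lab <- estimate_pairwise_labels(adj, 1)
  A <- adj$A
  h <- 1e-6
  num_grad <- function(fn) {
    g <- Z * 0
    for (i in seq_len(nrow(Z))) for (j in seq_len(ncol(Z))) {
      zp <- Z; zm <- Z
      zp[i, j] <- zp[i, j] + h
      zm[i, j] <- zm[i, j] - h
      g[i, j] <- (fn(zp) - fn(zm)) / (2 * h)
    }
    g
  }
  g_gc <- dgcn:::graph_center_grad(Z, A)
  expect_equal(g_gc, num_grad(function(z) graph_center_loss(z, A)),
               tolerance = 1e-5)
  g_pc <- dgcn:::pc_loss_impl(Z, lab$l, 1, want_grad = TRUE)$grad
  expect_equal(g_pc, num_grad(function(z) pseudo_contrastive_loss(z, lab$l, 1)),
               tolerance = 1e-5)
  g_ti <- dgcn:::ti_loss_impl(Z, Zp, want_grad = TRUE)$grad_Z
  expect_equal(g_ti, num_grad(function(z) transform_invariant_loss(z, Zp)),
               tolerance = 1e-5)
})
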