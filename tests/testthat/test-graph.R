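test_that("two-sample graph connects the only available pair", {
  adj <- build_knn_adjacency(matrix(c(0, 5), 2, 1), K = 1)
  expect_equal(adj$A, matrix(c(0, 1, 1, 0), 2, 2), ignore_attr = TRUE)
})

test_that("KNN edges match brute-force distance sorting on 1-D layouts", {
  # two tight pairs: symmetric edges exactly {1-2, 3-4}
  adj <- build_knn_adjacency(matrix(c(0, 1, 10, 11), 4, 1), K = 1)
  want <- matrix(0, 4, 4)
  want[1, 2] <- want[2, 1] <- want[3, 4] <- want[4, 3] <- 1
  expect_equal(adj$A, want, ignore_attr = TRUE)

  # on a 3-point line with K = 2 every other point is a neighbor
  adj <- build_knn_adjacency(matrix(c(0, 1, 2), 3, 1), K = 2)
  want <- matrix(1, 3, 3) - diag(3)
  expect_equal(adj$A, want, ignore_attr = TRUE)
})

test_that("directed adjacency has exactly K ones per row, self excluded", {
  rng <- rng_stream(4)
  F <- matrix(rng_rnorm(rng, 12 * 3), 12, 3)
  adj <- build_knn_adjacency(F, K = 4)
  expect_equal(rowSums(adj$A_directed), rep(4, 12))
  expect_equal(diag(adj$A_directed), rep(0L, 12))
  expect_equal(diag(adj$A), rep(0L, 12))
  expect_identical(adj$A, t(adj$A))
  for (k in 1:12) {
    expect_length(adj$neighbor_sets[[k]], 4)
    expect_false(k %in% adj$neighbor_sets[[k]])
  }
})

test_that("distance ties break toward the lowest index", {
  # rows 2 and 3 are equidistant from row 1
  F <- matrix(c(0, 1, -1, 5), 4, 1)
  adj <- build_knn_adjacency(F, K = 1)
  expect_equal(adj$neighbor_sets[[1]], 2L)
})

test_that("invalid K is rejected", {
  F <- matrix(rnorm(6), 3, 2)
  expect_error(build_knn_adjacency(F, 3), "invalid K")
  expect_error(build_knn_adjacency(F, 0), "invalid K")
})

test_that("degree normalization matches hand values and the dense oracle", {
  expect_equal(normalize_adjacency(diag(3)), diag(3))
  expect_equal(normalize_adjacency(matrix(1, 2, 2)), matrix(0.5, 2, 2))
  rng <- rng_stream(8)
  for (i in 1:20) {
    B <- 3 + (i %% 6)
    A <- matrix(rng_runif(rng, B * B) < 0.5, B, B) * 1
    A <- ((A + t(A)) > 0) * 1
    A <- A + diag(B)   # ensure positive degrees
    deg <- rowSums(A)
    oracle <- diag(1 / sqrt(deg)) %*% A %*% diag(1 / sqrt(deg))
    expect_equal(normalize_adjacency(A), oracle, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("zero-degree rows trigger the degenerate-graph error", {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 1
  expect_error(normalize_adjacency(A), "self-loops")
})

test_that("graph convolution reproduces hand-computed single layers", {
  cfg <- gcn_config(n_layers = 1, final_activation = TRUE, standardize_output = FALSE)
  gcn <- gcn_init(1, cfg, rng_stream(1))
  gcn$W[[1]] <- matrix(1, 1, 1)
  Ahat <- matrix(0.5, 2, 2)
  Z <- gcn_forward(matrix(c(2, 0), 2, 1), Ahat, gcn, normalized = TRUE)$Z
  expect_equal(Z, matrix(1, 2, 1), ignore_attr = TRUE)
  # ReLU clamps negative propagated values
  Z2 <- gcn_forward(matrix(c(-2, -2), 2, 1), diag(2), gcn, normalized = TRUE)$Z
  expect_equal(Z2, matrix(0, 2, 1), ignore_attr = TRUE)
})

test_that("multi-layer forward equals an independent step-by-step recomputation", {
  rng <- rng_stream(21)
  for (rep in 1:10) {
    B <- 4 + (rep %% 5)
    d <- 2 + (rep %% 4)
    F <- matrix(rng_rnorm(rng, B * d), B, d)
    cfg <- gcn_config(n_layers = 3, final_activation = FALSE, standardize_output = FALSE)
    gcn <- gcn_init(d, cfg, rng_stream(rep))
    adj <- build_knn_adjacency(F, K = 2)
    out <- gcn_forward(F, adj, gcn)$Z
    # plain dense recomposition
    Ahat <- normalize_adjacency(adj$A + diag(B))
    X <- F
    for (l in 1:3) {
      X <- Ahat %*% X %*% gcn$W[[l]]
      if (l < 3) X <- pmax(X, 0)
    }
    expect_equal(out, X, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("normalized adjacency eigenvalues lie in [-1, 1]", {
  rng <- rng_stream(31)
  for (rep in 1:15) {
    B <- 5 + (rep %% 8)
    F <- matrix(rng_rnorm(rng, B * 2), B, 2)
    adj <- build_knn_adjacency(F, K = min(3, B - 1))
    Ahat <- normalize_adjacency(adj$A + diag(B))
    ev <- eigen(Ahat, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-9 & ev <= 1 + 1e-9))
  }
})

test_that("constant input survives propagation on a regular graph with self-loops", {
  B <- 8
  A <- matrix(0, B, B)   # ring: every node has degree 2
  for (k in seq_len(B)) {
    A[k, (k %% B) + 1] <- 1
    A[(k %% B) + 1, k] <- 1
  }
  cfg <- gcn_config(n_layers = 1, final_activation = FALSE, standardize_output = FALSE)
  gcn <- gcn_init(1, cfg, rng_stream(2))
  gcn$W[[1]] <- matrix(1, 1, 1)
  X <- matrix(1, B, 1)
  Z <- gcn_forward(X, A, gcn)$Z
  expect_equal(Z, X, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("relabeling the batch permutes the embedding rows identically", {
  rng <- rng_stream(77)
  F <- matrix(rng_rnorm(rng, 10 * 4), 10, 4)
  cfg <- gcn_config(n_layers = 2)
  gcn <- gcn_init(4, cfg, rng_stream(3))
  perm <- c(4, 9, 1, 7, 2, 10, 3, 8, 5, 6)
  Z1 <- gcn_forward(F, build_knn_adjacency(F, 3), gcn)$Z
  Z2 <- gcn_forward(F[perm, ], build_knn_adjacency(F[perm, ], 3), gcn)$Z
  expect_equal(Z2, Z1[perm, ], tolerance = 1e-10)
})

test_that("dimension mismatches are configuration errors", {
  gcn <- gcn_init(4, gcn_config(), rng_stream(1))
  expect_error(gcn_forward(matrix(0, 3, 5), diag(3), gcn, normalized = TRUE),
               "configuration error")
  expect_error(gcn_forward(matrix(0, 3, 4), diag(4), gcn, normalized = TRUE),
               "configuration error")
})
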