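test_that("config invariants are enforced", {
  expect_error(train_config(batch_size = 2), "batch_size")
  expect_error(train_config(batch_size = 8, K = 8), "K must be <")
  expect_error(train_config(batch_size = 8, K = 0), "K must be >=")
  cfg <- train_config(K = 6)
  expect_equal(cfg$lambda, 3)   # default lambda = floor(K / 2)
})

test_that("identical config and seed reproduce the loss trace bit-for-bit", {
  set <- generate_dataset(tiny_spec(n = 6, seed = 2))
  cfg <- tiny_config(seed = 4, epochs = 2)
  s1 <- fit(set$images, cfg)
  s2 <- fit(set$images, cfg)
  expect_identical(s1$history, s2$history)
  expect_same_params(s1$encoder$params, s2$encoder$params)
  expect_same_params(s1$gcn$W, s2$gcn$W)
})

test_that("epoch batching drops the final partial batch", {
  set <- generate_dataset(synthetic_spec(n_per_grade = 20, image_size = 32,
                                         grades = 0:2, seed = 5))
  cfg <- train_config(batch_size = 16, K = 5, epochs = 2, seed = 1)
  st <- fit(set$images, cfg)   # floor(60 / 16) = 3 full batches per epoch
  expect_equal(st$step, 6L)
  expect_equal(nrow(st$history), 6L)
})

test_that("training needs at least one full batch", {
  set <- generate_dataset(tiny_spec(n = 2))
  expect_error(fit(set$images[1:5], tiny_config()), "insufficient data")
})

test_that("training is blind to labels by interface", {
  set <- generate_dataset(tiny_spec(n = 6, seed = 3))
  cfg <- tiny_config(seed = 7)
  s_images <- fit(set$images, cfg)       # plain image list
  s_set <- fit(set, cfg)                 # full set incl. grades
  expect_same_params(s_images$encoder$params, s_set$encoder$params)
  expect_identical(s_images$history, s_set$history)
})

test_that("checkpoint save/load resumes the trajectory bit-for-bit", {
  set <- generate_dataset(tiny_spec(n = 6, seed = 8))
  cfg <- tiny_config(seed = 9)
  st <- fit(set$images, cfg)
  path <- withr::local_tempfile(fileext = ".bin")
  save_checkpoint(st, path)
  st_loaded <- load_checkpoint(path)
  batch <- set$images[1:8]
  a <- train_step(batch, st, cfg)
  b <- train_step(batch, st_loaded, cfg)
  expect_same_params(a$state$encoder$params, b$state$encoder$params)
  expect_identical(a$report, b$report)
})

test_that("pre-update loss is reported and the parameters move", {
  set <- generate_dataset(tiny_spec(n = 4, seed = 10))
  cfg <- tiny_config(seed = 11)
  st <- init_training_state(cfg)
  obj <- prepare_step_objective(set$images[1:8], st, cfg)
  expected <- obj$value(obj$theta)
  r <- train_step(set$images[1:8], st, cfg)
  expect_equal(r$report$total, expected)
  expect_gt(max(abs(unlist(r$state$encoder$params) -
                      unlist(st$encoder$params))), 0)
})

test_that("training reduces the objective on a small synthetic set", {
  set <- generate_dataset(synthetic_spec(n_per_grade = 16, image_size = 32,
                                         grades = 0:2, seed = 12))
  cfg <- train_config(batch_size = 16, K = 5, epochs = 8, seed = 13)
  st <- fit(set$images, cfg)
  h <- st$history$total
  first <- mean(utils::head(h, 3))
  last <- mean(utils::tail(h, 3))
  expect_lt(last, first)
})

test_that("analytic step gradients match central differences", {
  set <- generate_dataset(tiny_spec(n = 4, seed = 14))
  cfg <- train_config(batch_size = 8, K = 3, epochs = 1, seed = 15,
                      encoder = encoder_config(feature_dim = 8))
  st <- init_training_state(cfg)
  obj <- prepare_step_objective(set$images[1:8], st, cfg)
  r <- obj$value_and_grad(obj$theta)
  h <- 1e-6
  idx <- round(seq(1, length(obj$theta), length.out = 12))
  for (i in idx) {
    tp <- obj$theta; tp[i] <- tp[i] + h
    tm <- obj$theta; tm[i] <- tm[i] - h
    num <- (obj$value(tp) - obj$value(tm)) / (2 * h)
    expect_equal(r$grad[i], num, tolerance = 1e-4)
  }
})

test_that("pseudo-labels after training beat the class-prior baseline", {
  set <- generate_dataset(synthetic_spec(n_per_grade = 16, image_size = 32,
                                         grades = 0:2, seed = 16))
  cfg <- train_config(batch_size = 16, K = 5, epochs = 8, seed = 17)
  st <- fit(set$images, cfg)
  f <- encode_batch(set$images, st$encoder)$features
  adj <- build_knn_adjacency(f, 8)
  lab <- estimate_pairwise_labels(adj, 4)
  up <- upper.tri(lab$l)
  same <- outer(set$grades, set$grades, "==")
  pos <- lab$l[up] == 1
  prior <- mean(same[up])
  expect_gt(sum(pos), 0)
  expect_gt(mean(same[up][pos]), prior)
})
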