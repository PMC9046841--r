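test_that("nearest-match prediction returns exact matches at distance zero", {
  rng <- rng_stream(16)
  Z <- matrix(rng_rnorm(rng, 6 * 4), 6, 4)
  gal <- manual_gallery(Z, c(0, 0, 1, 1, 2, 2))
  r <- predict_label(Z[3, ], gal)
  expect_equal(r$grade, 1L)
  expect_equal(r$distance, 0)
  expect_equal(r$matched_id, 3L)
})

test_that("nearest-match prediction matches a 1-D hand example", {
  gal <- manual_gallery(matrix(c(0, 10), 2, 1), c(0, 2))
  r <- predict_label(2, gal)
  expect_equal(r$grade, 0L)
  expect_equal(r$distance, 2)
})

test_that("prediction equals an exhaustive-scan 1-NN oracle", {
  rng <- rng_stream(17)
  Zg <- matrix(rng_rnorm(rng, 20 * 5), 20, 5)
  labs <- as.integer(rng_runif(rng, 20) < 0.5) * 2
  gal <- manual_gallery(Zg, labs)
  for (q in 1:50) {
    z <- rng_rnorm(rng, 5)
    r <- predict_label(z, gal)
    d <- apply(Zg, 1, function(row) sqrt(sum((row - z)^2)))
    j <- which.min(d)
    expect_equal(r$matched_id, j)
    expect_equal(r$grade, labs[j])
    expect_equal(r$distance, d[j], tolerance = 1e-12)
  }
})

test_that("distance ties resolve to the lowest gallery index", {
  gal <- manual_gallery(matrix(c(1, -1, 1), 3, 1), c(0, 1, 2))
  expect_equal(predict_label(0, gal)$matched_id, 1L)
})

test_that("gallery embedding covers every class deterministically", {
  st <- tiny_state()
  set <- generate_dataset(tiny_spec(n = 5))
  gal <- embed_gallery(set$images, set$grades, st)
  expect_equal(nrow(gal$Z), 15)
  expect_equal(gal$classes, 0:2)
  expect_identical(gal$labels, set$grades)   # labels pass through unmodified
  gal2 <- embed_gallery(set$images, set$grades, st)
  expect_identical(gal$Z, gal2$Z)
})

test_that("self-retrieval scores perfectly", {
  st <- tiny_state()
  set <- generate_dataset(tiny_spec(n = 5))
  gal <- embed_gallery(set$images, set$grades, st)
  # queries identical to gallery rows match themselves at distance ~0
  preds <- dgcn:::predict_batch(gal$Z, gal)
  expect_equal(preds$predicted_grade, set$grades)
  expect_equal(max(preds$match_distance), 0)
})

test_that("evaluation report conserves the query count and survives shuffling", {
  st <- tiny_state()
  set <- generate_dataset(tiny_spec(n = 8))
  sp <- split_gallery_query(set, 3, rng_stream(2))
  ev <- evaluate_dataset(sp$query$images, sp$query$grades,
                         embed_gallery(sp$gallery$images, sp$gallery$grades, st),
                         st)
  expect_equal(sum(ev$confusion), length(sp$query$images))
  perm <- rev(seq_along(sp$query$images))
  ev2 <- evaluate_dataset(sp$query$images[perm], sp$query$grades[perm],
                          embed_gallery(sp$gallery$images, sp$gallery$grades, st),
                          st)
  expect_equal(ev2$metrics$multiclass_accuracy, ev$metrics$multiclass_accuracy)
  expect_equal(ev2$metrics$sensitivity, ev$metrics$sensitivity)
  expect_equal(ev2$metrics$specificity, ev$metrics$specificity)
  expect_equal(ev2$roc$auc, ev$roc$auc)
})

test_that("referable scores need both gallery sides and an empty gallery errors", {
  rng <- rng_stream(18)
  Z <- matrix(rng_rnorm(rng, 4 * 2), 4, 2)
  gal_onesided <- manual_gallery(Z, c(2, 2, 3, 4))
  expect_error(referable_scores(Z, gal_onesided), "non-referable")
  gal_empty <- manual_gallery(Z[0, , drop = FALSE], integer(0))
  expect_error(predict_label(c(0, 0), gal_empty), "empty gallery")
})

test_that("embeddings table aligns with queries for external visualization", {
  st <- tiny_state()
  set <- generate_dataset(tiny_spec(n = 6))
  sp <- split_gallery_query(set, 2, rng_stream(3))
  gal <- embed_gallery(sp$gallery$images, sp$gallery$grades, st)
  ev <- evaluate_dataset(sp$query$images, sp$query$grades, gal, st)
  expect_equal(nrow(ev$embeddings), length(sp$query$images))
  expect_true(all(paste0("z", 1:16) %in% names(ev$embeddings)))
  expect_equal(ev$embeddings$grade, sp$query$grades)
})
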