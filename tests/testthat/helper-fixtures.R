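# Shared fixtures: everything is generated in code at test time.

tiny_spec <- function(seed = 1, n = 4, grades = 0:2, size = 32) {
  synthetic_spec(n_per_grade = n, image_size = size, grades = grades,
                 seed = seed)
}

tiny_config <- function(seed = 1, epochs = 1, ...) {
  train_config(batch_size = 8, K = 3, epochs = epochs, seed = seed, ...)
}

# a small trained-ish state without training (random init)
tiny_state <- function(seed = 1, ...) {
  init_training_state(tiny_config(seed = seed, ...))
}

# gallery_set built directly from an embedding matrix (for nearest-match
# tests that do not need images)
manual_gallery <- function(Z, labels) {
  structure(list(Z = Z, features = Z, labels = as.integer(labels),
                 classes = sort(unique(as.integer(labels)))),
            class = "gallery_set")
}

expect_same_params <- function(a, b, tol = 0) {
  expect_equal(unlist(a, use.names = FALSE), unlist(b, use.names = FALSE),
               tolerance = tol)
}
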