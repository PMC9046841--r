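test_that("spec validation enforces the severity-scale invariants", {
  expect_error(synthetic_spec(lesion_rate_by_grade = c(1, 2, 3, 4, 5)),
               "grade-0")
  expect_error(synthetic_spec(lesion_rate_by_grade = c(0, 5, 3, 8, 9)),
               "non-decreasing")
  expect_error(synthetic_spec(n_per_grade = 0), "n_per_grade")
  expect_error(synthetic_spec(image_size = 8), "image_size")
  expect_error(synthetic_spec(grades = c(0, 7)), "grades")
})

test_that("grade 0 images carry exactly zero lesions", {
  spec <- tiny_spec()
  rng <- rng_stream(5)
  for (i in 1:10) {
    im <- generate_image(0, spec, rng)
    expect_identical(attr(im, "lesion_count"), 0L)
    expect_identical(attr(im, "lesion_mass"), 0)
  }
})

test_that("unknown grades are rejected", {
  spec <- tiny_spec(grades = 0:2)
  expect_error(generate_image(4, spec, rng_stream(1)), "unknown grade")
})

test_that("images respect the shape and range contract", {
  spec <- tiny_spec(size = 32)
  rng <- rng_stream(2)
  im <- generate_image(2, spec, rng)
  expect_equal(dim(im), c(32, 32, 3))
  expect_true(all(im >= 0 & im <= 1))
})

test_that("generation is bit-identical under a fixed seed", {
  spec <- tiny_spec(seed = 9)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a$images, b$images)
  expect_identical(a$grades, b$grades)
})

test_that("dataset has n_per_grade images per grade, shuffled", {
  set <- generate_dataset(tiny_spec(n = 20, grades = 0:2))
  expect_length(set$images, 60)
  expect_equal(as.vector(table(set$grades)), rep(20, 3))
  # shuffling actually happened (grade-major order would be sorted)
  expect_false(all(diff(set$grades) >= 0))
})

test_that("Monte-Carlo lesion counts match the configured Poisson rate", {
  # 200 draws at the top grade; mean count within 3 standard errors of 12
  spec <- synthetic_spec(n_per_grade = 1, image_size = 32, grades = 0:4,
                         lesion_rate_by_grade = c(0, 1, 2, 6, 12), seed = 0)
  rng <- rng_stream(123)
  counts <- vapply(1:200, function(i) {
    attr(generate_image(4, spec, rng), "lesion_count")
  }, integer(1))
  se <- sqrt(12 / 200)
  expect_lt(abs(mean(counts) - 12), 3 * se)
})

test_that("mean lesion pixel mass increases strictly with grade", {
  set <- generate_dataset(tiny_spec(n = 20, grades = 0:4, seed = 3))
  mass <- tapply(set$meta$lesion_mass, set$meta$grade, mean)
  expect_true(all(diff(mass) > 0))
})

test_that("a trivial pixel-statistic classifier beats chance", {
  set <- generate_dataset(synthetic_spec(n_per_grade = 20, image_size = 64,
                                         grades = 0:2, seed = 4))
  stat <- vapply(set$images, pixel_grade_stat, numeric(1))
  centers <- tapply(stat, set$grades, mean)
  pred <- as.integer(names(centers))[
    apply(abs(outer(stat, centers, "-")), 1, which.min)]
  expect_gt(mean(pred == set$grades), 1 / 3)
})

test_that("gallery/query split is a disjoint cover with per-class counts", {
  set <- generate_dataset(tiny_spec(n = 20, grades = 0:2))
  sp <- split_gallery_query(set, 5, rng_stream(7))
  expect_length(sp$gallery$images, 15)
  expect_length(sp$query$images, 45)
  expect_equal(as.vector(table(sp$gallery$grades)), rep(5, 3))
  expect_length(intersect(sp$gallery$indices, sp$query$indices), 0)
  expect_setequal(c(sp$gallery$indices, sp$query$indices),
                  seq_along(set$images))
})

test_that("split is deterministic under a fixed stream and errors name the class", {
  set <- generate_dataset(tiny_spec(n = 6, grades = 0:2))
  a <- split_gallery_query(set, 2, rng_stream(11))
  b <- split_gallery_query(set, 2, rng_stream(11))
  expect_identical(a$gallery$indices, b$gallery$indices)
  expect_error(split_gallery_query(set, 6, rng_stream(1)),
               "class 0")
  # non-strict mode allows an empty query share
  sp <- split_gallery_query(set, 6, rng_stream(1), strict = FALSE)
  expect_length(sp$query$images, 0)
})

test_that("PNG round trip preserves grades and pixels to 8-bit precision", {
  set <- generate_dataset(tiny_spec(n = 2, grades = 0:1, size = 32))
  dir <- withr::local_tempdir()
  write_image_dir(set, dir)
  back <- read_image_dir(dir, manifest = file.path(dir, "manifest.tsv"))
  expect_equal(back$grades, set$grades)
  expect_equal(back$images[[1]], set$images[[1]], tolerance = 1 / 254,
               ignore_attr = TRUE)
})
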