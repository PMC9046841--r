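#' Specification of a synthetic graded fundus image set
#'
#' Describes a desk-scale stand-in for a retinopathy screening set: square RGB
#' images of a circular fundus field (optic disc, vessel arcs) whose lesion
#' load grows with severity grade on the five-level clinical scale
#' (none / mild / moderate / severe / proliferative). Nuisance variation in
#' illumination, contrast, and viewpoint is applied per image so that raw
#' pixel distance is an unreliable grade signal.
#'
#' Grade 0 always carries zero lesions (the scale defines it as "no
#' abnormalities"); lesion counts for the remaining grades are Poisson with a
#' non-decreasing mean per grade.
#'
#' @param n_per_grade images generated per severity grade (>= 1).
#' @param image_size pixels per side of the square image (>= 16).
#' @param grades ordered integer severity levels, a subset of 0:4.
#' @param lesion_rate_by_grade expected lesion count for grades 0..4
#'   (non-decreasing, first entry 0). Indexed by grade value, not by position
#'   in `grades`.
#' @param illumination_jitter relative brightness range (image is scaled by
#'   `1 + U(-j, j)`).
#' @param contrast_jitter relative contrast range about the image mean.
#' @param viewpoint_shift maximum fundus-center offset in pixels.
#' @param seed RNG seed; the full set is a pure function of the spec.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_grade = 60,
                           image_size = 64,
                           grades = 0:4,
                           lesion_rate_by_grade = c(0, 3, 14, 30, 50),
                           illumination_jitter = 0.15,
                           contrast_jitter = 0.15,
                           viewpoint_shift = 4,
                           seed = 0) {
  spec <- list(
    n_per_grade = as.integer(n_per_grade),
    image_size = as.integer(image_size),
    grades = as.integer(grades),
    lesion_rate_by_grade = as.numeric(lesion_rate_by_grade),
    illumination_jitter = illumination_jitter,
    contrast_jitter = contrast_jitter,
    viewpoint_shift = viewpoint_shift,
    seed = as.integer(seed)
  )
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  if (spec$n_per_grade < 1) stop("n_per_grade must be >= 1")
  if (spec$image_size < 16) stop("image_size must be >= 16")
  if (!all(spec$grades %in% 0:4)) stop("grades must lie in 0..4")
  if (anyDuplicated(spec$grades)) stop("grades must be distinct")
  r <- spec$lesion_rate_by_grade
  if (length(r) != 5) stop("lesion_rate_by_grade must give a rate for each grade 0..4")
  if (r[1] != 0) stop("grade-0 lesion rate must be 0 (no apparent retinopathy)")
  if (any(diff(r) < 0)) stop("lesion_rate_by_grade must be non-decreasing")
  if (spec$illumination_jitter < 0 || spec$contrast_jitter < 0 || spec$viewpoint_shift < 0) {
    stop("jitter / shift parameters must be non-negative")
  }
  invisible(spec)
}

# 3x3 box blur with zero padding, used to soften rasterized vessel polylines.
blur3 <- function(m, times = 1) {
  n <- nrow(m)
  p <- ncol(m)
  for (t in seq_len(times)) {
    pad <- matrix(0, n + 2, p + 2)
    pad[2:(n + 1), 2:(p + 1)] <- m
    m <- (pad[1:n, 1:p] + pad[1:n, 2:(p + 1)] + pad[1:n, 3:(p + 2)] +
          pad[2:(n + 1), 1:p] + pad[2:(n + 1), 2:(p + 1)] + pad[2:(n + 1), 3:(p + 2)] +
          pad[3:(n + 2), 1:p] + pad[3:(n + 2), 2:(p + 1)] + pad[3:(n + 2), 3:(p + 2)]) / 9
  }
  m
}

# Stamp an isotropic Gaussian bump of amplitude `amp` and scale `sigma` at
# (cx, cy) onto each listed channel of `img` (sign +1 bright, -1 dark).
# Returns the modified image and the stamped mass (sum of the bump).
stamp_blob <- function(img, cx, cy, sigma, amp, channel_weights, sign) {
  s <- dim(img)[1]
  w <- ceiling(3 * sigma)
  xs <- max(1, round(cx) - w):min(s, round(cx) + w)
  ys <- max(1, round(cy) - w):min(s, round(cy) + w)
  if (length(xs) == 0 || length(ys) == 0) {
    return(list(img = img, mass = 0))
  }
  g <- exp(-(outer((xs - cx)^2, (ys - cy)^2, "+")) / (2 * sigma^2))
  for (ch in 1:3) {
    img[xs, ys, ch] <- img[xs, ys, ch] + sign * amp * channel_weights[ch] * g
  }
  list(img = img, mass = amp * sum(g))
}

#' Generate one synthetic fundus-like image
#'
#' Draws a circular fundus field with radial shading, an optic-disc blob,
#' vessel-like dark arcs radiating from the disc, and a Poisson number of
#' small lesion blobs (dark hemorrhage-like and bright exudate-like) whose
#' expected count is `lesion_rate_by_grade[grade]`. Illumination, contrast,
#' and center-offset jitter are then applied.
#'
#' @param grade severity grade, must be a member of `spec$grades`.
#' @param spec a [synthetic_spec()].
#' @param rng a [rng_stream()]; all randomness is drawn from it.
#' @return `image_size` x `image_size` x 3 array in `[0, 1]`, with attributes
#'   `lesion_count` and `lesion_mass` recording the ground-truth lesion load.
#' @export
generate_image <- function(grade, spec, rng) {
  validate_synthetic_spec(spec)
  if (!(grade %in% spec$grades)) {
    stop(sprintf("unknown grade %s: spec covers grades {%s}",
                 grade, paste(spec$grades, collapse = ",")))
  }
  s <- spec$image_size
  half <- (s + 1) / 2

  off <- rng_runif(rng, 2, -spec$viewpoint_shift, spec$viewpoint_shift)
  cx <- half + off[1]
  cy <- half + off[2]
  r0 <- 0.47 * s

  xg <- matrix(seq_len(s), s, s)
  yg <- matrix(seq_len(s), s, s, byrow = TRUE)
  rr <- sqrt((xg - cx)^2 + (yg - cy)^2)
  mask <- rr <= r0

  img <- array(0, dim = c(s, s, 3))
  shade <- pmax(0, 1 - 0.35 * (rr / r0)^2)
  base_col <- c(0.74, 0.36, 0.12)
  for (ch in 1:3) img[, , ch] <- base_col[ch] * shade

  # optic disc: bright blob offset to one side of the macula center
  side <- if (rng_runif(rng, 1) < 0.5) -1 else 1
  oang <- rng_runif(rng, 1, -0.35, 0.35)
  ox <- cx + side * 0.58 * r0 * cos(oang)
  oy <- cy + side * 0.58 * r0 * sin(oang)
  img <- stamp_blob(img, ox, oy, sigma = 0.085 * s, amp = 1,
                    channel_weights = c(0.22, 0.42, 0.32), sign = +1)$img

  # vessel arcs: quadratic curves from the optic disc across the field
  canvas <- matrix(0, s, s)
  n_vessels <- 5L
  vpar <- rng_runif(rng, n_vessels * 4)
  tseq <- seq(0, 1, length.out = max(48L, 3L * s))
  for (v in seq_len(n_vessels)) {
    p <- vpar[(4 * (v - 1) + 1):(4 * v)]
    ang <- 2 * pi * p[1]
    endx <- cx + 0.92 * r0 * cos(ang)
    endy <- cy + 0.92 * r0 * sin(ang)
    ctrlx <- (ox + endx) / 2 + (p[2] - 0.5) * 0.5 * r0
    ctrly <- (oy + endy) / 2 + (p[3] - 0.5) * 0.5 * r0
    bx <- (1 - tseq)^2 * ox + 2 * (1 - tseq) * tseq * ctrlx + tseq^2 * endx
    by <- (1 - tseq)^2 * oy + 2 * (1 - tseq) * tseq * ctrly + tseq^2 * endy
    px <- pmin(pmax(round(bx), 1), s)
    py <- pmin(pmax(round(by), 1), s)
    canvas[cbind(px, py)] <- 1
  }
  canvas <- blur3(canvas, times = 2)
  if (max(canvas) > 0) canvas <- canvas / max(canvas)
  vessel_col <- c(0.32, 0.20, 0.06)
  for (ch in 1:3) img[, , ch] <- img[, , ch] - vessel_col[ch] * canvas

  # lesions: Poisson count with grade-specific mean; grade 0 draws rate 0
  rate <- spec$lesion_rate_by_grade[grade + 1]
  n_lesions <- rng_rpois(rng, 1, rate)
  lesion_mass <- 0
  if (n_lesions > 0) {
    lp <- matrix(rng_runif(rng, 5 * n_lesions), ncol = 5)
    for (i in seq_len(n_lesions)) {
      ang <- 2 * pi * lp[i, 1]
      rad <- 0.85 * r0 * sqrt(lp[i, 2])
      lx <- cx + rad * cos(ang)
      ly <- cy + rad * sin(ang)
      # lesion extent grows with severity: mild disease shows pinpoint
      # microaneurysms, higher grades show progressively larger
      # hemorrhage / exudate patches
      sigma <- 1.0 + 0.4 * grade + 0.6 * lp[i, 3]
      amp <- 0.6 + 0.25 * lp[i, 4]
      if (lp[i, 5] < 0.6) {
        st <- stamp_blob(img, lx, ly, sigma, amp, c(0.55, 0.30, 0.10), sign = -1)
      } else {
        st <- stamp_blob(img, lx, ly, sigma, amp, c(0.30, 0.30, 0.02), sign = +1)
      }
      img <- st$img
      lesion_mass <- lesion_mass + st$mass
    }
  }

  # nuisance: illumination scale, contrast about the in-field mean, mild noise
  illum <- 1 + rng_runif(rng, 1, -spec$illumination_jitter, spec$illumination_jitter)
  contr <- 1 + rng_runif(rng, 1, -spec$contrast_jitter, spec$contrast_jitter)
  img <- img * illum
  mfield <- mean(img[mask])
  img <- (img - mfield) * contr + mfield
  img <- img + array(rng_rnorm(rng, s * s * 3, 0, 0.01), dim = c(s, s, 3))

  for (ch in 1:3) img[, , ch] <- img[, , ch] * mask
  img <- pmin(pmax(img, 0), 1)
  attr(img, "lesion_count") <- as.integer(n_lesions)
  attr(img, "lesion_mass") <- lesion_mass
  img
}

#' Generate a full graded image set
#'
#' Produces `n_per_grade` images per grade, shuffles them, and records the
#' held-out ground truth. The result is a pure function of the spec (including
#' its seed).
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `graded_image_set`: list with `images` (list of
#'   H x W x 3 arrays), `grades` (integer vector), `meta` (data frame with
#'   per-image grade, lesion count and lesion mass), and `spec`.
#' @export
generate_dataset <- function(spec) {
  validate_synthetic_spec(spec)
  master <- rng_stream(spec$seed)
  img_rng <- rng_spawn(master, 1L)
  shuffle_rng <- rng_spawn(master, 2L)

  grades_all <- rep(spec$grades, each = spec$n_per_grade)
  images <- vector("list", length(grades_all))
  count <- integer(length(grades_all))
  mass <- numeric(length(grades_all))
  for (i in seq_along(grades_all)) {
    im <- generate_image(grades_all[i], spec, img_rng)
    count[i] <- attr(im, "lesion_count")
    mass[i] <- attr(im, "lesion_mass")
    attr(im, "lesion_count") <- NULL
    attr(im, "lesion_mass") <- NULL
    images[[i]] <- im
  }
  ord <- rng_sample(shuffle_rng, length(grades_all), length(grades_all))
  set <- list(
    images = images[ord],
    grades = grades_all[ord],
    meta = data.frame(
      id = sprintf("img_%04d", seq_along(ord)),
      grade = grades_all[ord],
      lesion_count = count[ord],
      lesion_mass = mass[ord]
    ),
    spec = spec
  )
  class(set) <- "graded_image_set"
  set
}

#' @export
print.graded_image_set <- function(x, ...) {
  cat(sprintf("graded_image_set: %d images (%dpx), grades {%s}\n",
              length(x$images), x$spec$image_size,
              paste(sort(unique(x$grades)), collapse = ",")))
  print(table(grade = x$grades))
  invisible(x)
}

#' Split a graded set into a labeled gallery and an unlabeled query set
#'
#' The gallery keeps its grade labels (it plays the role of the small
#' annotated reference set used at prediction time); the query set is the
#' disjoint remainder with its truth held out for evaluation only.
#'
#' @param set a `graded_image_set`.
#' @param gallery_per_class gallery members drawn per grade.
#' @param rng a [rng_stream()] used for the per-class draw.
#' @param strict if `TRUE` (default), a class whose query share would be empty
#'   is an error; if `FALSE`, equality with the class size is allowed.
#' @return list with elements `gallery` (images, grades) and `query`
#'   (images, grades, indices into `set`).
#' @export
split_gallery_query <- function(set, gallery_per_class, rng, strict = TRUE) {
  stopifnot(inherits(set, "graded_image_set"))
  classes <- sort(unique(set$grades))
  gal_idx <- integer(0)
  for (cl in classes) {
    members <- which(set$grades == cl)
    limit <- if (strict) gallery_per_class + 1 else gallery_per_class
    if (length(members) < limit) {
      stop(sprintf("insufficient data: class %d has %d members, need %s %d",
                   cl, length(members), if (strict) ">" else ">=", gallery_per_class))
    }
    gal_idx <- c(gal_idx, rng_sample(rng, members, gallery_per_class))
  }
  gal_idx <- sort(gal_idx)
  qry_idx <- setdiff(seq_along(set$images), gal_idx)
  list(
    gallery = list(images = set$images[gal_idx], grades = set$grades[gal_idx],
                   indices = gal_idx),
    query = list(images = set$images[qry_idx], grades = set$grades[qry_idx],
                 indices = qry_idx)
  )
}

#' High-frequency pixel statistic correlated with lesion load
#'
#' Mean absolute deviation of the image from a box-blurred copy, within the
#' fundus field. Lesions are small high-contrast blobs, so this grows with
#' lesion load; it is the "trivial classifier" statistic used to check that
#' generated sets carry a learnable grade signal.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @return scalar statistic.
#' @export
pixel_grade_stat <- function(image) {
  lum <- 0.5 * image[, , 1] + 0.35 * image[, , 2] + 0.15 * image[, , 3]
  sm <- blur3(lum, times = 2)
  field <- lum > 0.02
  if (!any(field)) return(0)
  mean(abs(lum - sm)[field])
}
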