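#' Family of label-preserving input transformations
#'
#' The invariance loss compares embeddings of an image and of a randomly
#' transformed copy. Admissible members must not change the grade semantics:
#' in-plane rotation about the image center and horizontal flips qualify for
#' macula-centered fundus fields.
#'
#' @param family character vector, subset of `c("rotation", "hflip")`; must be
#'   non-empty. Use `rotation_range = c(0, 0)` and no flip for an
#'   identity-only family.
#' @param rotation_range degrees, `c(min, max)` sampled uniformly per call.
#' @param hflip_prob probability of a horizontal flip when `"hflip"` is in the
#'   family.
#' @return object of class `transform_spec`.
#' @export
transform_spec <- function(family = "rotation",
                           rotation_range = c(-30, 30),
                           hflip_prob = 0.5) {
  if (length(family) == 0) stop("configuration error: transform family is empty")
  if (!all(family %in% c("rotation", "hflip"))) {
    stop("transform family members must be 'rotation' or 'hflip'")
  }
  if (length(rotation_range) != 2 || rotation_range[1] > rotation_range[2]) {
    stop("rotation_range must be c(min, max) with min <= max")
  }
  structure(list(family = family,
                 rotation_range = as.numeric(rotation_range),
                 hflip_prob = hflip_prob),
            class = "transform_spec")
}

# Bilinear rotation about the image center; out-of-field samples are 0
# (the fundus background). A 0-degree angle reproduces the input exactly.
rotate_image <- function(image, angle_deg) {
  d <- dim(image)
  s1 <- d[1]
  s2 <- d[2]
  th <- angle_deg * pi / 180
  c1 <- (s1 + 1) / 2
  c2 <- (s2 + 1) / 2
  xg <- matrix(seq_len(s1), s1, s2) - c1
  yg <- matrix(seq_len(s2), s1, s2, byrow = TRUE) - c2
  sx <- cos(th) * xg + sin(th) * yg + c1
  sy <- -sin(th) * xg + cos(th) * yg + c2

  x0 <- floor(sx)
  y0 <- floor(sy)
  fx <- sx - x0
  fy <- sy - y0

  out <- array(0, dim = d)
  # clamp corner indices; weight of out-of-range corners is forced to 0
  gather <- function(xi, yi, w) {
    ok <- xi >= 1 & xi <= s1 & yi >= 1 & yi <= s2
    xi <- pmin(pmax(xi, 1L), s1)
    yi <- pmin(pmax(yi, 1L), s2)
    idx <- cbind(as.vector(xi), as.vector(yi))
    w <- as.vector(w) * as.vector(ok)
    list(idx = idx, w = w)
  }
  g00 <- gather(x0, y0, (1 - fx) * (1 - fy))
  g10 <- gather(x0 + 1, y0, fx * (1 - fy))
  g01 <- gather(x0, y0 + 1, (1 - fx) * fy)
  g11 <- gather(x0 + 1, y0 + 1, fx * fy)
  for (ch in 1:3) {
    plane <- image[, , ch]
    v <- plane[g00$idx] * g00$w + plane[g10$idx] * g10$w +
         plane[g01$idx] * g01$w + plane[g11$idx] * g11$w
    out[, , ch] <- matrix(v, s1, s2)
  }
  out
}

#' Apply a randomly sampled label-preserving transformation
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param spec a [transform_spec()].
#' @param rng a [rng_stream()] supplying the transformation parameters.
#' @return transformed image with the same shape.
#' @export
apply_transform <- function(image, spec, rng) {
  stopifnot(inherits(spec, "transform_spec"))
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("invalid input: image must be an H x W x 3 array")
  }
  out <- image
  if ("rotation" %in% spec$family) {
    ang <- rng_runif(rng, 1, spec$rotation_range[1], spec$rotation_range[2])
    if (spec$rotation_range[1] == spec$rotation_range[2]) {
      ang <- spec$rotation_range[1]
    }
    if (ang != 0) out <- rotate_image(out, ang)
  }
  if ("hflip" %in% spec$family) {
    if (rng_runif(rng, 1) < spec$hflip_prob) {
      out <- out[, rev(seq_len(dim(out)[2])), , drop = FALSE]
    }
  }
  out
}
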