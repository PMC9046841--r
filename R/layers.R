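# Vectorized neural-network primitives on BLAS matrix products.
#
# Layout conventions:
#   spatial tensors  : array (H, W, C, B), column-major
#   feature matrices : matrix (B, d)
# Convolutions are 3x3 stride-1 zero-padded ("same"), realized by im2col:
# gathered patch matrices of shape (H*W*B, 9*C) times a (9*C, Cout) weight.
# im2col gather indices depend only on the tensor shape and are memoized.

.conv_memo <- new.env(parent = emptyenv())

conv_index <- function(H, W, C, B) {
  key <- paste(H, W, C, B, sep = "x")
  hit <- get0(key, envir = .conv_memo)
  if (!is.null(hit)) return(hit)
  H2 <- H + 2L
  W2 <- W + 2L
  HW <- H * W
  pix_i <- rep(seq_len(H), times = W)
  pix_j <- rep(seq_len(W), each = H)
  off_di <- rep(0:2, times = 3)
  off_dj <- rep(0:2, each = 3)
  base <- outer(pix_i, off_di, "+") + (outer(pix_j, off_dj, "+") - 1L) * H2
  idx <- matrix(0L, HW * B, 9L * C)
  plane <- H2 * W2
  for (cc in seq_len(C)) {
    for (o in 1:9) {
      colv <- base[, o] + (cc - 1L) * plane
      idx[, (cc - 1L) * 9L + o] <-
        rep(as.integer(colv), times = B) +
        rep((seq_len(B) - 1L) * plane * C, each = HW)
    }
  }
  assign(key, idx, envir = .conv_memo)
  idx
}

conv_forward <- function(x, W, b) {
  d <- dim(x)
  H <- d[1]; Wd <- d[2]; C <- d[3]; B <- d[4]
  HW <- H * Wd
  P <- array(0, dim = c(H + 2L, Wd + 2L, C, B))
  P[2:(H + 1), 2:(Wd + 1), , ] <- x
  idx <- conv_index(H, Wd, C, B)
  Xcol <- matrix(P[idx], nrow(idx), ncol(idx))
  Y <- Xcol %*% W
  Y <- Y + matrix(b, nrow(Y), ncol(Y), byrow = TRUE)
  Cout <- ncol(W)
  out <- aperm(array(Y, c(HW, B, Cout)), c(1, 3, 2))
  dim(out) <- c(H, Wd, Cout, B)
  list(out = out, cache = list(Xcol = Xcol, dim = d))
}

conv_backward <- function(dout, cache, W) {
  d <- cache$dim
  H <- d[1]; Wd <- d[2]; C <- d[3]; B <- d[4]
  HW <- H * Wd
  Cout <- ncol(W)
  dY3 <- array(dout, c(HW, Cout, B))
  dYmat <- matrix(aperm(dY3, c(1, 3, 2)), HW * B, Cout)
  dW <- crossprod(cache$Xcol, dYmat)
  db <- colSums(dYmat)
  dXcol <- tcrossprod(dYmat, W)
  idx <- conv_index(H, Wd, C, B)
  dPvec <- numeric((H + 2L) * (Wd + 2L) * C * B)
  # indices within one im2col column are distinct, so each pass is a plain
  # vectorized accumulate; overlap between offsets is handled across passes
  for (col in seq_len(ncol(idx))) {
    ii <- idx[, col]
    dPvec[ii] <- dPvec[ii] + dXcol[, col]
  }
  dP <- array(dPvec, c(H + 2L, Wd + 2L, C, B))
  dx <- dP[2:(H + 1), 2:(Wd + 1), , , drop = FALSE]
  list(dx = dx, grad = list(W = dW, b = db))
}

conv1_forward <- function(x, W, b) {
  d <- dim(x)
  H <- d[1]; Wd <- d[2]; C <- d[3]; B <- d[4]
  HW <- H * Wd
  M <- matrix(aperm(x, c(1, 2, 4, 3)), HW * B, C)
  Y <- M %*% W
  Y <- Y + matrix(b, nrow(Y), ncol(Y), byrow = TRUE)
  Cout <- ncol(W)
  out <- aperm(array(Y, c(HW, B, Cout)), c(1, 3, 2))
  dim(out) <- c(H, Wd, Cout, B)
  list(out = out, cache = list(M = M, dim = d))
}

conv1_backward <- function(dout, cache, W) {
  d <- cache$dim
  H <- d[1]; Wd <- d[2]; C <- d[3]; B <- d[4]
  HW <- H * Wd
  Cout <- ncol(W)
  dYmat <- matrix(aperm(array(dout, c(HW, Cout, B)), c(1, 3, 2)), HW * B, Cout)
  dW <- crossprod(cache$M, dYmat)
  db <- colSums(dYmat)
  dM <- tcrossprod(dYmat, W)
  dx <- aperm(array(dM, c(H, Wd, B, C)), c(1, 2, 4, 3))
  list(dx = dx, grad = list(W = dW, b = db))
}

relu_forward <- function(x) {
  list(out = pmax(x, 0), cache = x > 0)
}

relu_backward <- function(dout, mask) dout * mask

pool_forward <- function(x) {
  d <- dim(x)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0) {
    stop("average pooling requires even spatial dimensions, got ",
         d[1], "x", d[2])
  }
  io <- seq(1L, d[1], 2L)
  jo <- seq(1L, d[2], 2L)
  out <- (x[io, jo, , , drop = FALSE] + x[io + 1L, jo, , , drop = FALSE] +
          x[io, jo + 1L, , , drop = FALSE] + x[io + 1L, jo + 1L, , , drop = FALSE]) / 4
  list(out = out, cache = d)
}

pool_backward <- function(dout, d) {
  dx <- array(0, dim = d)
  io <- seq(1L, d[1], 2L)
  jo <- seq(1L, d[2], 2L)
  q <- dout / 4
  dx[io, jo, , ] <- q
  dx[io + 1L, jo, , ] <- q
  dx[io, jo + 1L, , ] <- q
  dx[io + 1L, jo + 1L, , ] <- q
  dx
}

gap_forward <- function(x) {
  d <- dim(x)
  HW <- d[1] * d[2]
  M <- matrix(x, HW, d[3] * d[4])
  cm <- colMeans(M)
  out <- t(matrix(cm, d[3], d[4]))
  list(out = out, cache = d)
}

gap_backward <- function(dout, d) {
  HW <- d[1] * d[2]
  dm <- matrix(rep(as.vector(t(dout)), each = HW) / HW, HW, d[3] * d[4])
  array(dm, dim = d)
}

# multi-level readout: global-average-pool the outputs of the tapped layers
# plus the incoming activation, z-score each pooled statistic across the
# batch (batch norm without affine), and concatenate
multi_gap_forward <- function(x, node, outs, frozen = NULL) {
  parts <- vector("list", length(node$taps) + 1)
  dims <- vector("list", length(node$taps) + 1)
  for (i in seq_along(node$taps)) {
    g <- gap_forward(outs[[node$taps[i]]])
    parts[[i]] <- g$out
    dims[[i]] <- g$cache
  }
  g <- gap_forward(x)
  parts[[length(parts)]] <- g$out
  dims[[length(dims)]] <- g$cache
  cat_out <- do.call(cbind, parts)
  bn <- batchstd_forward(cat_out, frozen = frozen)
  list(out = bn$out,
       cache = list(dims = dims, widths = vapply(parts, ncol, integer(1)),
                    bn = bn$cache))
}

multi_gap_backward <- function(dout, node, cache) {
  dcat <- batchstd_backward(dout, cache$bn)
  widths <- cache$widths
  ends <- cumsum(widths)
  starts <- ends - widths + 1
  n <- length(widths)
  pending <- vector("list", length(node$taps))
  for (i in seq_along(node$taps)) {
    pending[[i]] <- gap_backward(dcat[, starts[i]:ends[i], drop = FALSE],
                                 cache$dims[[i]])
  }
  dx <- gap_backward(dcat[, starts[n]:ends[n], drop = FALSE], cache$dims[[n]])
  list(dx = dx, pending = pending)
}

linear_forward <- function(x, W, b) {
  Y <- x %*% W
  Y <- Y + matrix(b, nrow(Y), ncol(Y), byrow = TRUE)
  list(out = Y, cache = x)
}

linear_backward <- function(dout, x, W) {
  list(dx = tcrossprod(dout, W),
       grad = list(W = crossprod(x, dout), b = colSums(dout)))
}

block_forward <- function(x, node, p) {
  r1 <- conv_forward(x, p$c1$W, p$c1$b)
  a1 <- relu_forward(r1$out)
  r2 <- conv_forward(a1$out, p$c2$W, p$c2$b)
  if (isTRUE(node$proj)) {
    rp <- conv1_forward(x, p$proj$W, p$proj$b)
    skip <- rp$out
    proj_cache <- rp$cache
  } else {
    skip <- x
    proj_cache <- NULL
  }
  a2 <- relu_forward(r2$out + skip)
  list(out = a2$out,
       cache = list(c1 = r1$cache, m1 = a1$cache, c2 = r2$cache,
                    proj = proj_cache, m2 = a2$cache))
}

block_backward <- function(dout, node, p, cache) {
  dpre <- relu_backward(dout, cache$m2)
  b2 <- conv_backward(dpre, cache$c2, p$c2$W)
  da1 <- relu_backward(b2$dx, cache$m1)
  b1 <- conv_backward(da1, cache$c1, p$c1$W)
  grad <- list(c1 = b1$grad, c2 = b2$grad)
  if (isTRUE(node$proj)) {
    bp <- conv1_backward(dpre, cache$proj, p$proj$W)
    grad$proj <- bp$grad
    dx <- b1$dx + bp$dx
  } else {
    dx <- b1$dx + dpre
  }
  list(dx = dx, grad = grad)
}

net_forward <- function(arch, params, x, frozen_bn = NULL) {
  caches <- vector("list", length(arch))
  # tapped layer outputs are kept for multi-level readout nodes
  tap_idx <- unlist(lapply(arch, function(nd) nd$taps))
  outs <- vector("list", length(arch))
  bn_stats <- NULL
  for (i in seq_along(arch)) {
    node <- arch[[i]]
    p <- params[[i]]
    r <- switch(node$type,
      conv = conv_forward(x, p$W, p$b),
      conv1 = conv1_forward(x, p$W, p$b),
      relu = relu_forward(x),
      pool = pool_forward(x),
      gap = gap_forward(x),
      multi_gap = multi_gap_forward(x, node, outs, frozen = frozen_bn),
      linear = linear_forward(x, p$W, p$b),
      block = block_forward(x, node, p),
      stop("unknown layer type: ", node$type))
    x <- r$out
    caches[[i]] <- r$cache
    if (node$type == "multi_gap") {
      bn_stats <- list(mu = r$cache$bn$mu, s = r$cache$bn$s)
    }
    if (i %in% tap_idx) outs[[i]] <- x
  }
  list(out = x, caches = caches, bn_stats = bn_stats)
}

net_backward <- function(arch, params, caches, dout) {
  grads <- vector("list", length(arch))
  pending <- vector("list", length(arch))   # tap gradients joining mid-chain
  for (i in rev(seq_along(arch))) {
    node <- arch[[i]]
    p <- params[[i]]
    cache <- caches[[i]]
    if (!is.null(pending[[i]])) dout <- dout + pending[[i]]
    r <- switch(node$type,
      conv = conv_backward(dout, cache, p$W),
      conv1 = conv1_backward(dout, cache, p$W),
      relu = list(dx = relu_backward(dout, cache), grad = NULL),
      pool = list(dx = pool_backward(dout, cache), grad = NULL),
      gap = list(dx = gap_backward(dout, cache), grad = NULL),
      multi_gap = {
        mg <- multi_gap_backward(dout, node, cache)
        for (t in seq_along(node$taps)) {
          ti <- node$taps[t]
          pending[[ti]] <- if (is.null(pending[[ti]])) mg$pending[[t]] else
            pending[[ti]] + mg$pending[[t]]
        }
        list(dx = mg$dx, grad = NULL)
      },
      linear = linear_backward(dout, cache, p$W),
      block = block_backward(dout, node, p, cache))
    dout <- r$dx
    grads[i] <- list(r$grad)   # [[<- would drop NULL slots
  }
  list(dx = dout, grads = grads)
}

# He-style initialization sized to each layer's fan-in.
init_net_params <- function(arch, rng) {
  lapply(arch, function(node) {
    switch(node$type,
      conv = list(
        W = matrix(rng_rnorm(rng, 9 * node$cin * node$cout, 0,
                             sqrt(2 / (9 * node$cin))),
                   9 * node$cin, node$cout),
        b = numeric(node$cout)),
      conv1 = list(
        W = matrix(rng_rnorm(rng, node$cin * node$cout, 0, sqrt(2 / node$cin)),
                   node$cin, node$cout),
        b = numeric(node$cout)),
      linear = list(
        W = matrix(rng_rnorm(rng, node$cin * node$cout, 0, sqrt(1 / node$cin)),
                   node$cin, node$cout),
        b = numeric(node$cout)),
      block = {
        p <- list(
          c1 = list(W = matrix(rng_rnorm(rng, 9 * node$cin * node$cout, 0,
                                         sqrt(2 / (9 * node$cin))),
                               9 * node$cin, node$cout),
                    b = numeric(node$cout)),
          c2 = list(W = matrix(rng_rnorm(rng, 9 * node$cout * node$cout, 0,
                                         sqrt(2 / (9 * node$cout))),
                               9 * node$cout, node$cout),
                    b = numeric(node$cout)))
        if (isTRUE(node$proj)) {
          p$proj <- list(W = matrix(rng_rnorm(rng, node$cin * node$cout, 0,
                                              sqrt(2 / node$cin)),
                                    node$cin, node$cout),
                         b = numeric(node$cout))
        }
        p
      },
      NULL)
  })
}
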