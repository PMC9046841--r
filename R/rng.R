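#' Deterministic random streams
#'
#' Every source of randomness in the package (image synthesis, parameter
#' initialization, mini-batch shuffling, transform sampling) draws from an
#' explicit stream object rather than the global generator, so one top-level
#' seed fans out to independent, serializable sub-streams and the whole
#' pipeline is bit-reproducible.
#'
#' @param seed integer seed.
#' @return an object of class `dgcn_rng` holding a private generator state.
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "Mersenne-Twister")
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "dgcn_rng"
  e
}

# Run expr with the stream's state installed, then capture the advanced state.
# The global generator is restored afterwards, so package randomness never
# perturbs user code.
rng_eval <- function(rng, expr) {
  stopifnot(inherits(rng, "dgcn_rng"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

#' Draw from a stream
#'
#' Stream-local counterparts of `runif`, `rnorm`, `rpois`, and `sample`:
#' they advance the given stream and leave the global generator untouched.
#'
#' @param rng a [rng_stream()].
#' @param n,min,max,mean,sd,lambda,x,size,replace as in the base functions.
#' @return as the corresponding base function.
#' @export
rng_runif <- function(rng, n, min = 0, max = 1) rng_eval(rng, stats::runif(n, min, max))

#' @rdname rng_runif
#' @export
rng_rnorm <- function(rng, n, mean = 0, sd = 1) rng_eval(rng, stats::rnorm(n, mean, sd))

#' @rdname rng_runif
#' @export
rng_rpois <- function(rng, n, lambda) rng_eval(rng, stats::rpois(n, lambda))

#' @rdname rng_runif
#' @export
rng_sample <- function(rng, x, size, replace = FALSE) {
  rng_eval(rng, sample(x, size = size, replace = replace))
}

#' Derive an independent child stream
#'
#' @param rng parent `dgcn_rng` stream.
#' @param label integer tag distinguishing siblings derived from one parent.
#' @return a new `dgcn_rng` stream whose trajectory is a deterministic function
#'   of the parent's current state and `label`.
#' @export
rng_spawn <- function(rng, label = 1L) {
  draw <- floor(rng_runif(rng, 1) * 2147483000)
  rng_stream((draw + 7919 * as.integer(label)) %% 2147483647)
}

# Serializable snapshot / restore, used by checkpoints.
rng_state <- function(rng) rng$state
rng_restore <- function(state) {
  e <- new.env(parent = emptyenv())
  e$state <- state
  class(e) <- "dgcn_rng"
  e
}
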