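#' Seeded random-number stream
#'
#' A self-contained random stream: draws from it never touch (and are never
#' influenced by) the global R RNG state, so a simulation is reproducible
#' from its seed alone and independent streams can coexist. Each simulation
#' run owns exactly one stream.
#'
#' @param seed integer seed; identical seeds yield identical sequences.
#' @return an object of class `rng_stream` (a mutable state holder).
#' @export
#' @examples
#' r <- rng_stream(1)
#' draw_turn(r)
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed)
  e$state <- local({
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    get(".Random.seed", envir = globalenv())
  })
  class(e) <- "rng_stream"
  e
}

#' Draw uniform variates from a stream
#'
#' @param rng an [rng_stream()]; its internal state advances.
#' @param n number of draws.
#' @param min,max bounds of the uniform distribution.
#' @return numeric vector of `n` draws.
#' @export
rng_uniform <- function(rng, n = 1L, min = 0, max = 1) {
  stopifnot(inherits(rng, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  assign(".Random.seed", rng$state, envir = globalenv())
  x <- stats::runif(n, min = min, max = max)
  rng$state <- get(".Random.seed", envir = globalenv())
  x
}

#' Snapshot / restore the state of a stream
#'
#' `rng_snapshot()` returns a plain, serializable copy of the stream state;
#' `rng_restore()` rebuilds an equivalent stream. Used by the world engine's
#' checkpoint machinery so that an interrupted run can be resumed
#' bit-for-bit.
#'
#' @param rng an [rng_stream()].
#' @return `rng_snapshot`: a list with `seed` and `state`;
#'   `rng_restore`: a new [rng_stream()].
#' @export
rng_snapshot <- function(rng) {
  stopifnot(inherits(rng, "rng_stream"))
  list(seed = rng$seed, state = rng$state)
}

#' @rdname rng_snapshot
#' @param snapshot a list as returned by `rng_snapshot()`.
#' @export
rng_restore <- function(snapshot) {
  e <- new.env(parent = emptyenv())
  e$seed <- snapshot$seed
  e$state <- snapshot$state
  class(e) <- "rng_stream"
  e
}
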