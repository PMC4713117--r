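#' Independent, replayable random-number streams
#'
#' A `rng_stream` carries its own `.Random.seed` state so that each pipeline
#' component (fold shuffling, GA variation, vote tie-breaking, balancing)
#' draws from a private stream. Drawing from one stream never perturbs the
#' global RNG or any other stream, which is what makes whole runs replayable
#' from a single seed.
#'
#' @param seed integer seed for the stream.
#' @return An object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", envir = globalenv())
  env$seed <- as.integer(seed)
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(env) <- "rng_stream"
  env
}

#' Evaluate an expression under a stream's RNG state
#'
#' Swaps the stream state into `.Random.seed`, evaluates `expr`, and swaps
#' the advanced state back out, restoring whatever global state existed.
#'
#' @param rng a [rng_stream()].
#' @param expr expression using R's RNG (`runif`, `sample`, ...).
#' @return The value of `expr`.
#' @export
with_stream <- function(rng, expr) {
  stopifnot(inherits(rng, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

#' @rdname with_stream
#' @param n number of deviates.
#' @export
stream_runif <- function(rng, n = 1L) with_stream(rng, stats::runif(n))

#' @rdname with_stream
#' @param x vector (or upper bound, see [sample()]) to sample from.
#' @param size sample size.
#' @param replace sample with replacement?
#' @export
stream_sample <- function(rng, x, size = length(x), replace = FALSE) {
  with_stream(rng, sample(x, size = size, replace = replace))
}

#' Derive named component seeds from one master seed
#'
#' Expands a single run seed into a deterministic set of per-component
#' seeds (`folds`, `ga`, `ties`, `balancing`, `data`, `models`) so each
#' stage can be replayed in isolation. All derived seeds stay below 2^31.
#'
#' @param seed master integer seed.
#' @return Named list of integer seeds.
#' @export
seed_streams <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  seed <- as.double(seed) %% 2147483647
  offs <- c(folds = 101L, ga = 211L, ties = 307L,
            balancing = 401L, data = 503L, models = 601L)
  out <- lapply(offs, function(o) as.integer((seed * 1103L + o * 12347) %% 2147483647))
  out
}
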