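# Named, independently seeded RNG streams.
#
# Each concern (stimulus draws, weight initialization, gap-junction kernel)
# gets its own stream so model variants see identical stimulus sequences.
# A stream stores its own .Random.seed and swaps it in around each draw;
# the caller's RNG state is untouched.

stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) * 7919L + as.integer(h %% 104729L)) %% 2147483587L
}

#' Create a named random-number stream
#'
#' @param seed Integer master seed.
#' @param name Stream name; distinct names give independent substreams of the
#'   same master seed.
#' @return An object of class `rng_stream`.
#' @examples
#' s <- rng_stream(1, "stimuli")
#' with_stream(s, runif(2))
#' @export
rng_stream <- function(seed, name = "default") {
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(stream_seed(seed, name))
  e$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  e$seed <- as.integer(seed)
  e$name <- name
  class(e) <- "rng_stream"
  e
}

#' Evaluate an expression under a stream's RNG state
#'
#' @param stream An [rng_stream()].
#' @param expr Expression performing random draws.
#' @return The value of `expr`; the stream's state is advanced, the global
#'   RNG state is restored.
#' @export
with_stream <- function(stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}
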