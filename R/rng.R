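#' Independently seedable random-number stream
#'
#' A small wrapper around R's Mersenne-Twister generator that keeps its own
#' generator state, so that several sources of randomness (e.g. an agent's
#' action sampling and the environment's outcome flips) can be advanced
#' independently without interfering with each other or with the global
#' RNG. Drawing from a stream saves and restores `.Random.seed`.
#'
#' @param seed Integer seed for this stream.
#' @return A list of draw functions: `runif(n)`, `sample_int(n, size)`
#'   (with replacement), and `permute(x)`.
#' @export
#' @examples
#' s <- rng_stream(1)
#' s$runif(2)
#' s$sample_int(4, 5)
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  state <- NULL
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    if (is.null(state)) set.seed(as.integer(seed) %% .Machine$integer.max)
    else assign(".Random.seed", state, globalenv())
    out <- f()
    state <<- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    out
  }
  list(
    runif = function(n) with_state(function() runif(n)),
    rnorm = function(n) with_state(function() stats::rnorm(n)),
    sample_int = function(n, size) with_state(function()
      sample.int(n, size, replace = TRUE)),
    permute = function(x) with_state(function() sample(x))
  )
}

# Derive a child seed (< 2^31) from a master seed and integer tags.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed) %% 2147483647
  for (t in tags) s <- (s * 69069 + as.double(t) * 12345 + 1) %% 2147483647
  as.integer(s)
}
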