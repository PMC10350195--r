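#' Deterministic random source
#'
#' All stochastic components of the package (corpus generation, augmentation,
#' model initialisation, batch shuffling) draw from an explicit random source
#' created by `make_rng()`. The source wraps an isolated Mersenne-Twister
#' stream, so concurrent sources never interfere with each other or with the
#' caller's global RNG state, and every run is bit-reproducible given its seed.
#'
#' @param seed Integer seed.
#' @return An object of class `pathner_rng`.
#' @examples
#' r <- make_rng(1L)
#' rng_runif(r, 3)
#' @export
make_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- new.env(parent = emptyenv())
  old <- .save_global_seed()
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", envir = globalenv())
  .restore_global_seed(old)
  env$seed <- as.integer(seed)
  class(env) <- "pathner_rng"
  env
}

.save_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Run `expr` under the rng's private stream, persisting the advanced state.
with_rng <- function(rng, expr) {
  stopifnot(inherits(rng, "pathner_rng"))
  old <- .save_global_seed()
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    .restore_global_seed(old)
  })
  expr
}

#' @rdname make_rng
#' @param rng A `pathner_rng` object.
#' @param n Number of draws.
#' @export
rng_runif <- function(rng, n = 1L) with_rng(rng, stats::runif(n))

#' @rdname make_rng
#' @param p Success probability.
#' @export
rng_bernoulli <- function(rng, n = 1L, p) with_rng(rng, stats::runif(n) < p)

#' @rdname make_rng
#' @param max Upper bound (inclusive) for integer draws.
#' @export
rng_int <- function(rng, n = 1L, max) with_rng(rng, sample.int(max, n, replace = TRUE))

#' @rdname make_rng
#' @param x Vector to permute.
#' @export
rng_permute <- function(rng, x) with_rng(rng, sample(x, length(x), replace = FALSE))

#' @rdname make_rng
#' @param lambda Poisson mean.
#' @export
rng_pois <- function(rng, n = 1L, lambda) with_rng(rng, stats::rpois(n, lambda))

#' @rdname make_rng
#' @param mean,sd Normal parameters.
#' @export
rng_norm <- function(rng, n = 1L, mean = 0, sd = 1) with_rng(rng, stats::rnorm(n, mean, sd))

# Derive a child seed (stable, below 2^31) for an independent sub-stream.
rng_child_seed <- function(rng) {
  as.integer(floor(with_rng(rng, stats::runif(1)) * 2147483646)) + 1L
}
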