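# Local RNG streams: every stochastic operation takes an explicit seed and
# draws from its own stream without disturbing the caller's .Random.seed.

.seeded_rng <- function(seed) {
  e <- new.env(parent = emptyenv())
  prev <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", globalenv())
  if (!is.null(prev)) assign(".Random.seed", prev, globalenv())
  else rm(".Random.seed", envir = globalenv())
  e
}

.with_rng <- function(rng, expr) {
  prev <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (!is.null(prev)) assign(".Random.seed", prev, globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

.sample_int <- function(rng, n, k, replace = FALSE)
  .with_rng(rng, sample.int(n, k, replace = replace))

.runif <- function(rng, n) .with_rng(rng, stats::runif(n))

.rnorm <- function(rng, n, sd = 1) .with_rng(rng, stats::rnorm(n, sd = sd))

.rpois <- function(rng, n, lambda) .with_rng(rng, stats::rpois(n, lambda))

# derive a distinct child seed from a base seed (kept within 32-bit range)
.child_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + 104729 * k) %% 2147483647
}
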