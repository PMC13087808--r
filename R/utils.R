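## Seeded RNG streams and small helpers.
##
## Every stochastic operation in the package draws from an isolated RNG stream
## created by local_rng(seed), so results are reproducible per seed and never
## perturb (nor depend on) the caller's global RNG state.

local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  g <- globalenv()
  old <- get0(".Random.seed", envir = g, inherits = FALSE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  env$state <- get(".Random.seed", envir = g)
  if (!is.null(old)) assign(".Random.seed", old, envir = g)
  else suppressWarnings(rm(".Random.seed", envir = g))

  with_state <- function(f) {
    function(...) {
      outer <- get0(".Random.seed", envir = g, inherits = FALSE)
      assign(".Random.seed", env$state, envir = g)
      on.exit({
        env$state <- get(".Random.seed", envir = g)
        if (!is.null(outer)) assign(".Random.seed", outer, envir = g)
        else suppressWarnings(rm(".Random.seed", envir = g))
      })
      f(...)
    }
  }
  list(
    sample_int = with_state(function(n, size = n, replace = FALSE, prob = NULL)
      sample.int(n, size, replace = replace, prob = prob)),
    runif  = with_state(stats::runif),
    rnorm  = with_state(stats::rnorm),
    rbinom = with_state(stats::rbinom)
  )
}

## stable 32-bit string hash (FNV-style, exact in double arithmetic)
str_hash32 <- function(x) {
  vapply(x, function(s) {
    h <- 2166136261
    for (c in utf8ToInt(s)) h <- ((h * 16777619) %% 4294967296 + c) %% 4294967296
    h
  }, numeric(1), USE.NAMES = FALSE)
}

## derive a per-stage seed (< 2^31) from a master seed and a stage label
derive_seed <- function(master, stage) {
  as.integer((str_hash32(stage) + as.numeric(master) * 2654435761) %% 2147483647)
}

## mix integers into a 32-bit hash (for fingerprints)
int_hash32 <- function(ints) {
  h <- 2166136261
  for (v in ints) h <- ((h * 16777619) %% 4294967296 + (v %% 4294967296)) %% 4294967296
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a
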