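#' @importFrom rlang %||% abort
#' @importFrom stats rnorm runif quantile sd cor median setNames
#' @importFrom utils head tail
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. All stochastic operations in the
# package route through this so that every result is a pure function of its
# named seed.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` child seeds from one parent seed, each < 2^31, reproducibly.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
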