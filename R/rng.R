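#' Evaluate an expression under a local, restorable random seed
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a single explicit seed fully determines every result
#' and no global RNG state leaks between calls.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  code
}

#' Derive a child seed from a parent seed and a stream index
#'
#' Deterministic splitting of one user-facing seed into independent streams
#' (one per simulation component, model repeat, permutation block, ...).
#' Arithmetic stays below 2^53 so the result is exact in double precision,
#' and the returned seed is always a valid 32-bit integer.
#'
#' @param seed parent integer seed.
#' @param stream non-negative stream index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), is.numeric(stream), stream >= 0)
  m <- 2147483647 # 2^31 - 1 (prime)
  s <- (abs(seed) %% 94906265)
  as.integer(((s * 48271 + stream * 12345 + 1) %% (m - 1)) + 1)
}
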