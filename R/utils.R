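#' Derive a named sub-seed from a master seed
#'
#' All stochastic components (dataset split, shuffling, weight initialization,
#' phantom synthesis) draw from per-purpose generators so that enabling or
#' disabling one component never perturbs the random stream of another. The
#' derived seed is a deterministic hash of the master seed and a purpose label,
#' kept inside the 32-bit integer range.
#'
#' @param seed integer master seed.
#' @param purpose character label, e.g. `"init"`, `"shuffle"`, `"split"`.
#' @param index optional non-negative integer mixed into the hash (epoch or
#'   sample index).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, purpose, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(purpose))
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  v <- (abs(as.numeric(seed)) %% m)
  v <- (v * 48271 + h * 16807 + as.numeric(index) * 69621 + 1) %% m
  v <- (v * 48271 + 12345) %% m
  as.integer(v %% (m - 1) + 1)
}

#' Evaluate an expression under a local RNG state
#'
#' Saves and restores `.Random.seed` so deterministic helpers do not disturb
#' the caller's random stream.
#'
#' @param seed integer seed for the local stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
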