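# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals never
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed for a named stream, kept below 2^31.
stream_seed <- function(seed, stream) {
  offsets <- c(structural = 1L, functional = 2L, betas = 3L, motion = 4L,
               graph = 5L, permutation = 6L, pipeline = 7L, rsa = 8L)
  off <- offsets[[stream]]
  ((as.numeric(seed) %% 536870909) * 7 + off * 104729) %% 2147483647
}

assert_square_labelled <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square matrix, got ", nrow(m), "x", ncol(m), call. = FALSE)
  }
  invisible(m)
}

assert_symmetric <- function(m, what = "matrix", tol = 1e-10) {
  assert_square_labelled(m, what)
  if (max(abs(m - t(m))) > tol) {
    stop(what, " must be symmetric", call. = FALSE)
  }
  invisible(m)
}

# Strict upper-triangle vector in column-major order (the canonical pair
# order used for thresholding tie-breaks and RDM comparisons).
upper_vec <- function(m) m[upper.tri(m)]

# Rebuild a symmetric matrix (zero diagonal) from an upper-triangle vector.
sym_from_upper <- function(v, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- v
  m + t(m)
}
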