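#' Derive a reproducible sub-seed from a base seed and a salt
#'
#' All randomness in the package flows from one run seed. Independent random
#' streams (layer initialisation, minibatch shuffles, noise draws) use seeds
#' derived deterministically from the base seed and a string salt, so that
#' adding an optional component (for example a variational log-variance head)
#' does not perturb the random stream of unrelated components.
#'
#' @param seed integer base seed.
#' @param salt character scalar naming the stream.
#' @return an integer in \[1, 2147483646\].
#' @export
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  x <- abs(as.numeric(seed)) %% 2147483647
  for (ch in utf8ToInt(paste0(salt))) {
    x <- (x * 69069 + ch) %% 2147483647
  }
  as.integer(x %% 2147483646) + 1L
}

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded helpers do not disturb
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# internal: stop with a formatted message
abort <- function(...) stop(sprintf(...), call. = FALSE)

# internal: check a scalar probability-like weight vector
check_prob_vector <- function(w, what = "weights", tol = 1e-12) {
  if (any(w < 0)) abort("%s must be nonnegative", what)
  if (abs(sum(w) - 1) > tol) abort("%s must sum to 1 (got %.15g)", what, sum(w))
  invisible(TRUE)
}
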