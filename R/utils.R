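# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the Mersenne-Twister stream, evaluates
#' `code`, and restores the previous state so that seeded operations do not
#' perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  code
}

# Deterministically derive a child seed from a base seed and integer tags.
# Keeps results in [0, 2^31 - 2] so they are valid R integer seeds.
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (tag in c(...)) {
    h <- (h * 48271 + as.numeric(tag) + 1) %% m
  }
  as.integer(h)
}

stop2 <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "mdwgan_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_finite_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x))
    stop2("mdwgan_format_error", "%s must be a numeric matrix", what)
  if (any(!is.finite(x)))
    stop2("mdwgan_format_error", "%s contains missing or non-finite entries", what)
  invisible(x)
}
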