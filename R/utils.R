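#' Evaluate an expression with a local, restored RNG state
#'
#' All stochastic functions in this package draw their randomness from one
#' explicit integer seed per call; the caller's global RNG state is restored
#' afterwards, so seeded calls are bit-reproducible and side-effect free.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(as.integer(seed))
  code
}

#' Specification of additive observation noise
#'
#' @param sd standard deviation in the units of the observable; >= 0
#' @param seed integer seed; identical seed and parameters give bit-identical
#'   generator output
#' @return an object of class `noise_spec`
#' @export
noise_spec <- function(sd = 0, seed = 1) {
  stopifnot(is.numeric(sd), length(sd) == 1L, sd >= 0)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(sd = sd, seed = as.integer(seed)), class = "noise_spec")
}
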