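#' Named random-number substreams
#'
#' All stochastic operations in the package draw from a substream derived from
#' a root seed and a short operation name, so each module is reproducible on
#' its own: re-running one generator with the same root seed yields the same
#' output regardless of what else has consumed random numbers in the session.
#'
#' The derivation is a small deterministic string hash folded into the root
#' seed; it is not cryptographic, it only needs to map distinct names to
#' distinct, platform-stable seeds below 2^31.
#'
#' @param seed integer root seed.
#' @param name substream label, e.g. "trios" or "perm".
#' @return An integer seed in [0, 2^31 - 1].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (k in utf8ToInt(as.character(name))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer((abs(as.numeric(seed)) * 2654435 + h) %% 2147483647)
}

#' Evaluate an expression under a named substream
#'
#' Saves and restores the caller's RNG state, so substream draws never perturb
#' surrounding code.
#'
#' @param seed integer root seed.
#' @param name substream label.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  expr
}
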