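#' Deterministic seed derivation
#'
#' Derives a reproducible sub-seed from a base seed and a string key, so that
#' independent random streams (fold split, negative sampling, parameter
#' initialisation, per-document generation) never share state. The result is
#' always a valid 32-bit R seed.
#'
#' @param seed integer base seed.
#' @param key character key naming the stream.
#' @return a single integer in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(as.character(key))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Run expr under a local RNG state; the caller's RNG is untouched.
with_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

spanrel_log <- function(stage, ...) {
  if (isTRUE(getOption("spanrel.verbose", FALSE))) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  invisible(NULL)
}
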