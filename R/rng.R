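# Deterministic seed derivation.  R lacks a splittable RNG, so per-trajectory
# seeds are derived from the master seed and structural indices (repeat,
# ratio, stage, tag) by multiply-accumulate hashing mod 2^31 - 1.  Within a
# trajectory a single sequential stream is used; fluctuation and compensation
# draws interleave in a fixed order, so they cannot alias across components.

#' Derive a child seed from a master seed and indices
#'
#' Deterministically mixes a master seed with any number of integer (or
#' string) labels into a seed in `[1, 2^31 - 2]`.  Used throughout the
#' simulation engines so that every (repeat, ratio, stage) cell has an
#' independent, reproducible random stream.
#'
#' @param seed master seed, a non-negative integer.
#' @param ... integers or short strings identifying the child stream.
#' @return an integer seed usable with [set.seed()].
#' @examples
#' mix_seed(1, 3, "fluct")
#' @export
mix_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  h <- (seed %% m)
  for (x in list(...)) {
    if (is.character(x)) {
      x <- sum(utf8ToInt(x) * seq_along(utf8ToInt(x)))
    }
    for (xi in x) {
      h <- (h * 48271 + (xi %% m) + 1) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

# Run `expr` under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  expr
}
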