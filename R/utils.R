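#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state, restoring .Random.seed afterwards.
# All seeded operations in the package go through this so that user RNG
# state is never clobbered.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    set.seed(seed)
  }
  force(code)
}

#' Derive a child seed from a master seed and a stage tag
#'
#' Pure function of its arguments: the same master seed and tag always give
#' the same child seed, and different tags give (with high probability)
#' different child seeds. Results stay inside the 32-bit integer range.
#'
#' @param seed master seed (integer).
#' @param tag character tag naming the consumer (stage, session, fold ...).
#' @return an integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (k in utf8ToInt(paste(tag, collapse = "/"))) {
    h <- (h * 131 + k) %% m
  }
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

# round-half-up (stats::round is round-half-even); used for exact design counts
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
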