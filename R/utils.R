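# Internal helpers shared across the package.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded package internals never
#' disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic per-stage seed derivation from a single user seed.
# Keeps results < 2^31 so set.seed() always accepts them.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.double(seed) * 7919 + as.double(stage) * 104729) %% 2147483629
}

# Most frequent value with deterministic tie-breaking by `levels` order.
mode_value <- function(x, levels) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_character_)
  counts <- table(factor(x, levels = levels))
  levels[which.max(counts)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
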