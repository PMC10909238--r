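#' @keywords internal
"_PACKAGE"

# Run code under a local RNG stream seeded with `seed`, restoring the caller's
# .Random.seed afterwards. All user-facing randomness in the package flows
# through this helper so that no function disturbs global RNG state.
with_local_seed <- function(seed, code) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Half-up rounding to `digits` decimals, applied to the represented double
# (base round() is half-to-even on exact ties, e.g. 98.125 -> 98.12; the
# tabulation convention here rounds such ties up, 98.125 -> 98.13). Values
# whose decimal form is a tie but whose double sits below it (2.675 is stored
# as 2.67499...) follow the double, matching how printed tables are produced.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Clip a position matrix (m x d) row-wise to box bounds given as vectors.
clip_box <- function(P, lower, upper) {
  P <- pmax(P, matrix(lower, nrow(P), ncol(P), byrow = TRUE))
  pmin(P, matrix(upper, nrow(P), ncol(P), byrow = TRUE))
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
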