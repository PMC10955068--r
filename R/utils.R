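#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library calls never perturb user RNG.
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
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Pipeline stages (scene generation, detector simulation, tiling, splits)
#' each draw from their own sub-stream so a stage can be re-run independently
#' yet reproducibly. The derivation is a fixed Lehmer step modulo 2^31 - 1,
#' keeping results inside the 32-bit integer range `set.seed()` accepts.
#'
#' @param seed master seed (integer).
#' @param k sub-stream index (non-negative integer).
#' @return an integer seed.
#' @export
#' @examples
#' derive_seed(42, 1)
derive_seed <- function(seed, k) {
  m <- 2147483647
  s <- (as.double(seed) %% m) + 1
  for (i in seq_len(k + 1L)) {
    s <- (48271 * s) %% m
  }
  as.integer(s)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# round-half-up at `digits` decimals; base round() is round-half-even, which
# disagrees with reported two-decimal tables on exact .xx5 values
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}
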