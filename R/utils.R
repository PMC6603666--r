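#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite integer.")
  }
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
  expr
}

# Derive a stream of child seeds from one master seed, each < 2^31.
# Double arithmetic keeps the products exact (< 2^53) for any 32-bit seed.
derive_seeds <- function(seed, n) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 7919 + 104729 * seq_len(n)) %% 2147483647)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

# Linear interpolation over a logical mask of samples to replace; endpoints
# fall back to the nearest kept value.
interp_masked <- function(x, mask) {
  if (!any(mask)) return(x)
  if (all(mask)) return(x)
  idx <- seq_along(x)
  x[mask] <- approx(idx[!mask], x[!mask], xout = idx[mask], rule = 2)$y
  x
}

signal_rms <- function(x) sqrt(mean(x^2))
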