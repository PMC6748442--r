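#' Moment-ratio skewness
#'
#' Uncorrected sample skewness `g1 = m3 / m2^(3/2)`, where `m2` and `m3` are
#' the second and third central moments with divisor `n`. This is the plain
#' moment-ratio estimator; at the sample sizes used throughout the package
#' (10^4 and up) small-sample bias corrections are negligible.
#'
#' @param x Numeric vector.
#' @param na.rm Drop missing values first?
#' @return A single numeric value, `NA` if fewer than 2 distinct values or
#'   zero variance.
#' @export
#' @examples
#' moment_skewness(rexp(1e4))   # positive
moment_skewness <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

# Run an expression under a temporary RNG state when a seed is given.
# Leaves the caller's RNG untouched in that case; with seed = NULL the
# expression simply advances the global RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic stream of sub-seeds derived from one master seed.
# Keeps every derived seed strictly below 2^31.
derive_seeds <- function(master_seed, n) {
  with_seed_if(master_seed, sample.int(.Machine$integer.max - 1L, n))
}
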