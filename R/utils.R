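# Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions are pure in their
#' declared `seed` argument and never disturb the caller's RNG stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Derive a child seed from (seed, index); stays below 2^31 - 1.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919) %% 2147483587L)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

# Moving average with shrinking (partial) windows at the edges; k must be odd.
moving_average <- function(x, k) {
  n <- length(x)
  h <- (k - 1L) %/% 2L
  i <- seq_len(n)
  lo <- pmax(1L, i - h); hi <- pmin(n, i + h)
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
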