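#' Evaluate an expression under a fixed RNG seed
#'
#' Saves the current state of R's random number generator, seeds it with
#' `seed`, evaluates `expr`, and restores the previous state on exit. All
#' stochastic operations in the package funnel through this helper so that a
#' fixed seed yields bit-identical output without disturbing the caller's
#' RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# scalar validators -----------------------------------------------------------

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < lo) || any(x > hi))
    stop(sprintf("`%s` must lie in [%g, %g]", name, lo, hi), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

#' Convert 1-based inclusive intervals to 0-based half-open (BED) and back
#'
#' Internal coordinates throughout the package are 1-based inclusive
#' (chr:pos style); BED files on disk are 0-based half-open. These two
#' helpers centralise the conversion.
#'
#' @param start,end Interval bounds.
#' @return A two-column data.frame of converted bounds.
#' @keywords internal
to_bed_coords <- function(start, end) {
  data.frame(start = start - 1L, end = end)
}

#' @rdname to_bed_coords
#' @keywords internal
from_bed_coords <- function(start, end) {
  data.frame(start = start + 1L, end = end)
}

# log-sum-exp over the columns of a matrix (rows are independent problems)
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}
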