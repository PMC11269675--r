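# Internal helpers shared across modules.

DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
GROWING_MONTHS <- 4:9  # April-September, Northern Hemisphere

#' Evaluate an expression with a temporary RNG state
#'
#' Sets the seed (fixed Mersenne-Twister kind) for the duration of `expr` and
#' restores the caller's RNG state afterwards, so no function leaks global
#' random state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (abs(seed) >= 2^31) stop("seed must be a 32-bit integer")
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
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Sub-seed derivation: keeps every stage seed below 2^31 and decorrelated.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 31L + as.integer(offset)) %% 2147483587L
}

#' Weighted mean and population-style weighted standard deviation
#'
#' Frequency-weight moments: the SD uses the weighted second central moment
#' divided by the total weight (not n-1), so a single observation has SD 0.
#'
#' @param x numeric values.
#' @param w non-negative weights, same length.
#' @return list with `mean` and `sd`.
#' @export
#' @examples
#' weighted_moments(c(1800, 2000), c(100, 300))
weighted_moments <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  m <- sum(w * x) / sum(w)
  v <- sum(w * (x - m)^2) / sum(w)
  list(mean = m, sd = sqrt(v))
}

# Smooth pseudo-terrain field: white noise passed through a separable
# moving-average filter, rescaled to unit SD. Deterministic under the
# caller's RNG state.
smooth_field <- function(nr, nc, window = 7L) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  # two 1-D moving-average passes with edge replication
  smooth1 <- function(v) {
    n <- length(v)
    idx <- pmin(pmax(outer(seq_len(n), seq_len(window) - (window + 1) %/% 2, `+`), 1), n)
    rowMeans(matrix(v[idx], n, window))
  }
  z <- apply(z, 2, smooth1)
  z <- t(apply(z, 1, smooth1))
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- z / s
  z
}

# fail with a consistent message when required columns are missing
check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
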