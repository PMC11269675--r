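#' Percentile-winsorized scaling of one indicator column
#'
#' `AC_i = (X - Q5) / (Q95 - Q5)` with the 5th and 95th percentiles (linear
#' interpolation between order statistics) as thresholds, clamped to [0, 1]
#' to damp outliers. Columns whose benefit direction is `lower_is_better`
#' are inverted (`1 - scaled`). A degenerate column (Q5 == Q95) maps to all
#' 0 with a warning.
#'
#' @param x numeric indicator values across regions.
#' @param direction `"higher_is_better"` or `"lower_is_better"`.
#' @param probs the two percentile thresholds (default 0.05, 0.95).
#' @return numeric scores in [0, 1].
#' @export
#' @examples
#' percentile_scale(0:100)[51] # (50 - 5) / (95 - 5)
percentile_scale <- function(x, direction = c("higher_is_better",
                                              "lower_is_better"),
                             probs = c(0.05, 0.95)) {
  direction <- match.arg(direction)
  if (all(is.na(x))) stop("all-missing indicator column")
  if (any(!is.finite(x))) stop("non-finite indicator values")
  q <- stats::quantile(x, probs = probs, names = FALSE, type = 7)
  if (q[2] == q[1]) {
    warning("degenerate indicator column (Q5 == Q95): scored 0")
    return(rep(0, length(x)))
  }
  s <- pmin(1, pmax(0, (x - q[1]) / (q[2] - q[1])))
  if (direction == "lower_is_better") 1 - s else s
}

#' Scale a full indicator table
#'
#' Applies [percentile_scale()] column-wise with each indicator's direction.
#'
#' @param table data.frame with `region_id` and indicator columns.
#' @param directions named character vector of directions per indicator;
#'   defaults to the table's `directions` attribute, falling back to
#'   [ac_indicator_info()].
#' @return data.frame `region_id` + scaled columns in [0, 1]; attribute
#'   `n_degenerate` counts constant columns.
#' @export
scale_indicators <- function(table, directions = NULL) {
  check_columns(table, "region_id", "indicator table")
  cols <- setdiff(names(table), "region_id")
  if (!length(cols)) stop("no indicator columns")
  if (is.null(directions)) directions <- attr(table, "directions")
  if (is.null(directions)) {
    info <- ac_indicator_info()
    directions <- stats::setNames(info$direction, info$indicator)
  }
  miss <- setdiff(cols, names(directions))
  if (length(miss)) {
    stop("no direction defined for indicator(s): ", paste(miss, collapse = ", "))
  }
  n_degenerate <- 0L
  scaled <- lapply(cols, function(cn) {
    withCallingHandlers(
      percentile_scale(table[[cn]], directions[[cn]]),
      warning = function(w) {
        if (grepl("degenerate", conditionMessage(w))) {
          n_degenerate <<- n_degenerate + 1L
          invokeRestart("muffleWarning")
        }
      }
    )
  })
  out <- data.frame(region_id = table$region_id, stringsAsFactors = FALSE)
  out[cols] <- scaled
  attr(out, "n_degenerate") <- n_degenerate
  out
}

#' Aggregate scaled indicators into the adaptive-capacity score
#'
#' Weighted mean of the scaled indicator scores per region (default equal
#' weights, the main-analysis choice), optionally followed by a cross-region
#' min-max rescale to [0, 1]. Dimension means (social / physical / natural /
#' human / financial) are reported alongside for profiling.
#'
#' @param scaled output of [scale_indicators()].
#' @param weights optional non-negative per-indicator weights (named or in
#'   column order); default equal.
#' @param normalize apply the final min-max rescale (default TRUE).
#' @param info indicator metadata mapping indicators to dimensions.
#' @return data.frame: `region_id`, `ac_raw` (pre-rescale weighted mean),
#'   `ac`, and `dim_<dimension>` means.
#' @export
aggregate_capacity <- function(scaled, weights = NULL, normalize = TRUE,
                               info = ac_indicator_info()) {
  cols <- setdiff(names(scaled), "region_id")
  m <- as.matrix(scaled[cols])
  if (is.null(weights)) weights <- rep(1, length(cols))
  if (!is.null(names(weights))) {
    miss <- setdiff(cols, names(weights))
    if (length(miss)) stop("weights missing for: ", paste(miss, collapse = ", "))
    weights <- weights[cols]
  }
  if (length(weights) != length(cols)) {
    stop(sprintf("weight length %d != %d indicators", length(weights),
                 length(cols)))
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative and not all zero")
  }
  w <- weights / sum(weights)
  out <- data.frame(region_id = scaled$region_id,
                    ac_raw = as.numeric(m %*% w), stringsAsFactors = FALSE)
  out$ac <- if (normalize) minmax_scale(out$ac_raw) else out$ac_raw
  for (d in unique(info$dimension)) {
    dc <- intersect(info$indicator[info$dimension == d], cols)
    if (length(dc)) {
      out[[paste0("dim_", d)]] <- rowMeans(m[, dc, drop = FALSE])
    }
  }
  out
}

#' Saaty random consistency index
#'
#' @param n matrix order (1..15).
#' @return the random index RI(n).
#' @export
saaty_ri <- function(n) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
          1.51, 1.54, 1.56, 1.57, 1.59)
  if (n < 1 || n > length(ri)) stop("RI table defined for n in 1..15")
  ri[n]
}

#' AHP weights from a pairwise-comparison matrix
#'
#' Principal-eigenvector weights by power iteration (tolerance 1e-10), the
#' principal eigenvalue, and the consistency ratio
#' `CR = ((lambda_max - n) / (n - 1)) / RI(n)`.
#'
#' @param A square positive reciprocal matrix (`a_ji = 1/a_ij`, unit
#'   diagonal, checked to a relative tolerance of 1e-6).
#' @param tol convergence tolerance of the power iteration.
#' @return list: `weights` (summing to 1), `lambda_max`, `cr`.
#' @export
#' @examples
#' w <- c(0.5, 0.3, 0.2)
#' ahp_weights(outer(w, w, `/`))$weights
ahp_weights <- function(A, tol = 1e-10) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (n != ncol(A)) stop("pairwise matrix must be square")
  if (any(!is.finite(A)) || any(A <= 0)) {
    stop("pairwise matrix must be strictly positive")
  }
  if (max(abs(A * t(A) - 1)) > 1e-6) {
    stop("matrix is not reciprocal (a_ji != 1/a_ij)")
  }
  if (max(abs(diag(A) - 1)) > 1e-8) stop("diagonal must be 1")
  w <- rep(1 / n, n)
  for (it in seq_len(10000L)) {
    w_new <- as.numeric(A %*% w)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  lambda <- mean(as.numeric(A %*% w) / w)
  cr <- if (n <= 2) 0 else ((lambda - n) / (n - 1)) / saaty_ri(n)
  list(weights = stats::setNames(w, rownames(A)), lambda_max = lambda,
       cr = cr)
}

#' Consistency gate for AHP judgements
#'
#' Accepts a set of pairwise comparisons iff its consistency ratio is
#' strictly below 10%.
#'
#' @param cr consistency ratio (>= 0 up to numerical noise).
#' @return logical; a rejection attaches a `message` attribute naming the
#'   threshold.
#' @export
check_consistency <- function(cr) {
  if (!is.finite(cr)) stop("CR must be finite")
  ok <- cr < 0.10
  if (!ok) {
    attr(ok, "message") <- sprintf(
      "consistency ratio %.3f rejected: judgements must satisfy CR < 0.10", cr)
  }
  ok
}

#' Rank concordance between expert weight vectors
#'
#' Spearman rank correlation between every pair of expert indicator-weight
#' vectors, the agreement diagnostic for region-specific AHP surveys.
#'
#' @param weight_sets list (length >= 2) of equal-length numeric vectors, or
#'   a matrix with one expert per row.
#' @return symmetric correlation matrix.
#' @export
weight_concordance <- function(weight_sets) {
  if (is.matrix(weight_sets)) {
    weight_sets <- lapply(seq_len(nrow(weight_sets)),
                          function(i) weight_sets[i, ])
  }
  if (length(weight_sets) < 2) stop("need >= 2 weight sets")
  len <- vapply(weight_sets, length, integer(1))
  if (length(unique(len)) != 1) stop("weight sets differ in length")
  W <- do.call(cbind, weight_sets)
  colnames(W) <- names(weight_sets) %||% paste0("expert", seq_along(weight_sets))
  stats::cor(W, method = "spearman")
}
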