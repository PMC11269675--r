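#' Linear min-max scaling to [0, 1]
#'
#' `(x - min) / (max - min)`; with `invert = TRUE`, `(max - x) / (max - min)`.
#' Degenerate input (all values equal) maps to all 0: a column with no
#' differential signal contributes nothing.
#'
#' @param x numeric vector (>= 1 finite value).
#' @param invert flip the scale.
#' @return numeric vector in [0, 1].
#' @export
#' @examples
#' minmax_scale(c(2, 4, 6))
#' minmax_scale(c(2, 4, 6), invert = TRUE)
minmax_scale <- function(x, invert = FALSE) {
  if (!length(x)) stop("minmax_scale: empty input")
  if (any(!is.finite(x))) stop("minmax_scale: non-finite values")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  s <- (x - rng[1]) / (rng[2] - rng[1])
  if (invert) 1 - s else s
}

#' Adverse-direction index changes between two periods
#'
#' Differences per region between future and present regional bioclimatic
#' records, signed so that the adverse direction is positive: warming raises
#' `d_hi` and `d_cni`, and drying (a *decrease* of the Dryness Index) raises
#' `d_di = DI_present - DI_future`.
#'
#' @param present,future data.frames from [regional_bioclim()] with matching
#'   `region_id` sets.
#' @return data.frame: `region_id`, `d_hi`, `d_cni`, `d_di`.
#' @export
adverse_delta <- function(present, future) {
  check_columns(present, c("region_id", "hi", "cni", "di"), "present")
  check_columns(future, c("region_id", "hi", "cni", "di"), "future")
  if (!setequal(present$region_id, future$region_id) ||
      nrow(present) != nrow(future)) {
    stop("present and future cover different regions")
  }
  fut <- future[match(present$region_id, future$region_id), ]
  data.frame(region_id = present$region_id,
             d_hi = fut$hi - present$hi,
             d_cni = fut$cni - present$cni,
             d_di = present$di - fut$di,
             stringsAsFactors = FALSE)
}

#' Regional climate-change exposure
#'
#' Scales each adverse index delta across regions with linear min-max
#' normalization (0 = smallest change, 1 = greatest change) and averages the
#' three scaled components into the exposure score. With `mode = "absolute"`
#' the deltas are replaced by their magnitudes before scaling.
#'
#' @param deltas data.frame from [adverse_delta()].
#' @param mode `"signed"` (default: adverse-direction deltas as-is) or
#'   `"absolute"`.
#' @return data.frame: `region_id`, the deltas, `e_hi`, `e_cni`, `e_di`,
#'   `exposure`, all components in [0, 1].
#' @export
exposure_index <- function(deltas, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  check_columns(deltas, c("region_id", "d_hi", "d_cni", "d_di"), "deltas")
  if (nrow(deltas) < 2) {
    warning("single region: min-max scale is degenerate, all components 0")
  }
  d <- deltas[, c("d_hi", "d_cni", "d_di")]
  if (mode == "absolute") d <- abs(d)
  scaled <- vapply(d, minmax_scale, numeric(nrow(deltas)))
  scaled <- matrix(scaled, nrow = nrow(deltas))
  out <- deltas
  out$e_hi <- scaled[, 1]; out$e_cni <- scaled[, 2]; out$e_di <- scaled[, 3]
  out$exposure <- rowMeans(scaled)
  out
}

#' Ensemble spread across pseudo-GCM members
#'
#' Per-cell inter-member range (max - min) and standard deviation of the
#' annual mean temperature and annual mean monthly precipitation, the model
#' agreement diagnostic for the future scenario fields.
#'
#' @param members list (length >= 2) of field lists with `tas` and `pr`
#'   arrays of shape `[12, rows, cols]` (e.g. `climate$members$ssp370`).
#' @return list of matrices `tas_range`, `tas_sd`, `pr_range`, `pr_sd`
#'   (rows x cols).
#' @export
ensemble_spread <- function(members) {
  if (length(members) < 2) stop("ensemble_spread needs >= 2 members")
  summarize <- function(var) {
    maps <- lapply(members, function(m) apply(m[[var]], c(2, 3), mean))
    arr <- simplify2array(maps)                  # rows x cols x K
    list(range = apply(arr, c(1, 2), function(v) max(v) - min(v)),
         sd = apply(arr, c(1, 2), stats::sd))
  }
  ts <- summarize("tas"); ps <- summarize("pr")
  list(tas_range = ts$range, tas_sd = ts$sd,
       pr_range = ps$range, pr_sd = ps$sd)
}
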