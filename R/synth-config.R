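#' Configuration for the synthetic study-system generator
#'
#' Bundles every knob of the synthetic data generator that emulates the
#' pipeline's inputs: a gridded monthly climatology for a present period and a
#' ladder of three future scenarios, contiguous winegrowing regions, grape
#' varieties with known climatic optima, cultivation areas with macro-region
#' indirection and synonym aliasing, and a correlated 15-indicator
#' adaptive-capacity table.
#'
#' The future scenarios are built as `ssp126` / `ssp370` / `ssp585`, scaling
#' `warming_delta_C` and the precipitation change by 0.5 / 1 / 1.5 so the
#' ladder orders scenarios by severity.
#'
#' @param grid_shape integer (rows, cols) of the climate grid.
#' @param lat_range numeric (south, north) latitude span in degrees N;
#'   row 1 of the grid is the northernmost row.
#' @param lon_origin western edge longitude in degrees E.
#' @param cell_size_deg longitudinal cell size in degrees.
#' @param n_regions number of winegrowing regions (>= 3: tertile
#'   classification needs at least three values).
#' @param n_varieties number of grape varieties.
#' @param n_macro_regions number of macro statistical units used for
#'   cultivation-area indirection (0 disables macro-level rows).
#' @param n_countries number of coarse country blocks.
#' @param n_members pseudo-GCM ensemble members for the default scenario
#'   (>= 2 enables the spread diagnostic; members average exactly to the
#'   scenario field).
#' @param member_spread SD (degrees C / mm) of the member perturbations.
#' @param warming_delta_C mean warming of the `ssp370` scenario, degrees C.
#' @param warming_gradient relative north-south modulation of the warming
#'   field (0 = spatially uniform warming).
#' @param precip_factor multiplicative precipitation change of `ssp370`.
#' @param noise_sd SD of the cell-level noise on present fields (degrees C
#'   for temperatures, scaled x4 for precipitation in mm/month).
#' @param future_noise_sd SD of additional seeded noise on future fields
#'   (default 0: future fields are exact transforms of the present).
#' @param synonym_rate fraction of cultivation-table variety mentions
#'   replaced by an alias.
#' @param orphan_rate fraction of aliases absent from the synonym table
#'   (these mentions stay unmatched, emulating real-world match loss).
#' @param macro_share fraction of (variety, macro) cultivation groups
#'   reported at macro-region level instead of region level.
#' @param kernel_bw bandwidth (standardized index units) of the Gaussian
#'   kernel that concentrates a variety's cultivation area near its optimum.
#' @param indicator_corr target pairwise correlation among the 15
#'   adaptive-capacity indicator columns; must lie in (-1/14, 1).
#' @param region_size integer (min, max) region size in cells.
#' @param seed integer master seed; all randomness derives from it.
#'
#' @return an object of class `synth_config` (a validated list).
#' @export
#' @examples
#' cfg <- synth_config(n_regions = 10, seed = 42)
#' cfg$scenarios$ssp585$warming
synth_config <- function(grid_shape = c(40L, 50L),
                         lat_range = c(36, 52),
                         lon_origin = -5,
                         cell_size_deg = 0.25,
                         n_regions = 60L,
                         n_varieties = 24L,
                         n_macro_regions = 6L,
                         n_countries = 8L,
                         n_members = 5L,
                         member_spread = 0.6,
                         warming_delta_C = 3,
                         warming_gradient = 0.3,
                         precip_factor = 0.85,
                         noise_sd = 0.5,
                         future_noise_sd = 0,
                         synonym_rate = 0.2,
                         orphan_rate = 0.1,
                         macro_share = 0.3,
                         kernel_bw = 0.7,
                         indicator_corr = 0.3,
                         region_size = c(4L, 12L),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2 || any(!is.finite(grid_shape)) || any(grid_shape <= 0)) {
    stop("grid_shape must be two positive integers (rows, cols)")
  }
  if (length(lat_range) != 2 || lat_range[1] >= lat_range[2]) {
    stop("lat_range must be (south, north) with south < north")
  }
  if (n_regions < 3) stop("n_regions must be >= 3 (tertiles need >= 3 values)")
  if (n_varieties < 1) stop("n_varieties must be >= 1")
  if (n_macro_regions < 0) stop("n_macro_regions must be >= 0")
  if (synonym_rate < 0 || synonym_rate > 1) stop("synonym_rate must be in [0, 1]")
  if (orphan_rate < 0 || orphan_rate > 1) stop("orphan_rate must be in [0, 1]")
  if (macro_share < 0 || macro_share > 1) stop("macro_share must be in [0, 1]")
  if (abs(indicator_corr) >= 1) stop("|indicator_corr| must be < 1")
  if (indicator_corr <= -1 / 14) {
    stop("indicator_corr must exceed -1/14 for a valid 15-variable correlation matrix")
  }
  if (noise_sd < 0 || future_noise_sd < 0) stop("noise SDs must be >= 0")
  if (precip_factor < 0) stop("precip_factor must be >= 0")
  if (n_regions * region_size[1] > prod(grid_shape)) {
    stop("grid too small for n_regions regions of the minimum size")
  }
  if (abs(seed) >= 2^31) stop("seed must fit in a 32-bit integer")

  # scenario ladder: severity multipliers on warming and on (1 - precip_factor)
  mult <- c(ssp126 = 0.5, ssp370 = 1, ssp585 = 1.5)
  scenarios <- lapply(mult, function(m) {
    list(warming = warming_delta_C * m,
         precip_factor = max(0, 1 - (1 - precip_factor) * m))
  })

  structure(list(
    grid_shape = grid_shape, lat_range = lat_range, lon_origin = lon_origin,
    cell_size_deg = cell_size_deg, n_regions = as.integer(n_regions),
    n_varieties = as.integer(n_varieties),
    n_macro_regions = as.integer(n_macro_regions),
    n_countries = as.integer(n_countries), n_members = as.integer(n_members),
    member_spread = member_spread, warming_delta_C = warming_delta_C,
    warming_gradient = warming_gradient, precip_factor = precip_factor,
    noise_sd = noise_sd, future_noise_sd = future_noise_sd,
    synonym_rate = synonym_rate, orphan_rate = orphan_rate,
    macro_share = macro_share, kernel_bw = kernel_bw,
    indicator_corr = indicator_corr,
    region_size = as.integer(region_size), seed = as.integer(seed),
    default_scenario = "ssp370", scenarios = scenarios
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synthetic study-system configuration\n")
  cat(sprintf("  grid: %d x %d cells, lat %.1f-%.1f N\n",
              x$grid_shape[1], x$grid_shape[2], x$lat_range[1], x$lat_range[2]))
  cat(sprintf("  regions: %d | varieties: %d | macro units: %d | countries: %d\n",
              x$n_regions, x$n_varieties, x$n_macro_regions, x$n_countries))
  cat(sprintf("  ssp370: +%.1f C, precip x%.2f | members: %d | noise sd %.2f\n",
              x$warming_delta_C, x$precip_factor, x$n_members, x$noise_sd))
  cat(sprintf("  synonym rate %.2f (orphans %.2f) | macro share %.2f | seed %d\n",
              x$synonym_rate, x$orphan_rate, x$macro_share, x$seed))
  invisible(x)
}
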