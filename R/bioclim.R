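#' Huglin day-length coefficient
#'
#' Stepwise latitude correction of the Huglin heliothermal index. The default
#' table: <= 40 deg N -> 1.00, 40-42 -> 1.02, 42-44 -> 1.03, 44-46 -> 1.04,
#' 46-48 -> 1.05, 48-50 -> 1.06, 50-60 -> 1.06 (flat extension). Latitudes at
#' or beyond 60 deg N are outside the published range and raise an error.
#'
#' @param lat latitude in degrees N (vectorized).
#' @return numeric coefficient(s) K.
#' @export
#' @examples
#' huglin_k(c(38, 45, 49))
huglin_k <- function(lat) {
  if (any(!is.finite(lat))) stop("latitude must be finite")
  if (any(lat >= 60)) {
    stop("Huglin day-length coefficient undefined at latitude >= 60 N")
  }
  if (any(lat < 0)) stop("Southern-Hemisphere latitudes are not supported")
  breaks <- c(-Inf, 40, 42, 44, 46, 48, 60)
  k <- c(1.00, 1.02, 1.03, 1.04, 1.05, 1.06)
  k[findInterval(lat, breaks, left.open = TRUE)]
}

#' Huglin heliothermal index from monthly climatologies
#'
#' Monthly approximation of the Huglin index: over April-September,
#' `HI = sum max(0, ((tas - 10) + (tasmax - 10)) / 2) * N_month * K(lat)`
#' with `N_month` the number of days and `K` the day-length coefficient.
#' The `max(0, .)` clamp is applied at month level (an unclamped variant is
#' available via `clamp = FALSE`).
#'
#' @param tas,tasmax monthly mean and maximum temperature (degrees C): a
#'   length-12 vector (calendar months) or a `12 x n` matrix of cells.
#' @param lat latitude in degrees N (scalar or length n).
#' @param clamp clamp negative monthly contributions to zero (default TRUE).
#' @param k_fun day-length coefficient function of latitude.
#' @return numeric HI (degree C . days), length n; non-negative when clamped.
#' @export
#' @examples
#' tas <- rep(0, 12); tasmax <- rep(0, 12)
#' tas[7] <- 20; tasmax[7] <- 26
#' huglin_index(tas, tasmax, lat = 45) # ((10 + 16)/2) * 31 * 1.04
huglin_index <- function(tas, tasmax, lat, clamp = TRUE, k_fun = huglin_k) {
  tas <- as_month_matrix(tas); tasmax <- as_month_matrix(tasmax)
  if (!identical(dim(tas), dim(tasmax))) stop("tas and tasmax shapes differ")
  contrib <- ((tas[GROWING_MONTHS, , drop = FALSE] - 10) +
                (tasmax[GROWING_MONTHS, , drop = FALSE] - 10)) / 2
  if (clamp) contrib <- pmax(contrib, 0)
  days <- DAYS_IN_MONTH[GROWING_MONTHS]
  hi <- colSums(contrib * days)
  hi * k_fun(lat)
}

#' Cool Night Index
#'
#' The mean September minimum temperature, an indicator of night-time
#' ripening conditions.
#'
#' @param tasmin monthly minimum temperature (degrees C): length-12 vector or
#'   `12 x n` matrix.
#' @return numeric CNI (degrees C), length n.
#' @export
#' @examples
#' cool_night_index(c(rep(5, 8), 12, rep(5, 3)))
cool_night_index <- function(tasmin) {
  tasmin <- as_month_matrix(tasmin)
  cni <- tasmin[9, ]
  if (any(!is.finite(cni))) stop("September tasmin is missing or non-finite")
  cni
}

#' Parameters of the Riou dryness-index water balance
#'
#' @param Wo initial (and maximum) soil water reserve, mm.
#' @param k_monthly vegetation absorption coefficient for April-September.
#' @param evap_days_divisor mm of rain per effective bare-soil evaporation
#'   day (JPm = min(N, pr / divisor)).
#' @return a `di_params` list.
#' @export
di_params <- function(Wo = 200,
                      k_monthly = c(0.1, 0.3, 0.5, 0.5, 0.5, 0.5),
                      evap_days_divisor = 5) {
  if (Wo <= 0) stop("Wo must be positive")
  if (length(k_monthly) != length(GROWING_MONTHS)) {
    stop("k_monthly must have one value per growing-season month (Apr-Sep)")
  }
  if (any(k_monthly < 0 | k_monthly > 1)) stop("k must lie in [0, 1]")
  if (evap_days_divisor <= 0) stop("evap_days_divisor must be positive")
  structure(list(Wo = Wo, k_monthly = k_monthly,
                 evap_days_divisor = evap_days_divisor),
            class = "di_params")
}

#' Dryness Index (potential soil water balance)
#'
#' Riou-style monthly water balance over April-September. Starting from the
#' full reserve `Wo`, each month removes vine transpiration
#' `Tv = k * PET` and bare-soil evaporation
#' `Es = (PET / N) * (1 - k) * JPm` with `JPm = min(N, pr / divisor)`, adds
#' precipitation, and caps the reserve at `Wo`. The reserve after September
#' is the Dryness Index; it may be negative (strong potential deficit) but
#' never exceeds `Wo`.
#'
#' @param pr monthly precipitation (mm): length-12 vector or `12 x n` matrix.
#' @param pet monthly potential evapotranspiration (mm), same shape; see
#'   [estimate_pet()].
#' @param params a [di_params()] object.
#' @return numeric DI (mm), length n; `DI <= Wo`.
#' @export
#' @examples
#' dryness_index(rep(0, 12), rep(0, 12)) # no fluxes: DI stays at Wo = 200
dryness_index <- function(pr, pet, params = di_params()) {
  pr <- as_month_matrix(pr); pet <- as_month_matrix(pet)
  if (!identical(dim(pr), dim(pet))) stop("pr and pet shapes differ")
  if (any(pet < 0)) stop("PET must be non-negative")
  if (any(pr < 0)) stop("precipitation must be non-negative")
  W <- rep(params$Wo, ncol(pr))
  for (j in seq_along(GROWING_MONTHS)) {
    m <- GROWING_MONTHS[j]
    N <- DAYS_IN_MONTH[m]
    k <- params$k_monthly[j]
    Tv <- k * pet[m, ]
    JPm <- pmin(N, pr[m, ] / params$evap_days_divisor)
    Es <- (pet[m, ] / N) * (1 - k) * JPm
    W <- pmin(params$Wo, W + pr[m, ] - Tv - Es)
  }
  W
}

#' Monthly potential evapotranspiration (Hargreaves)
#'
#' Temperature-only Hargreaves estimate:
#' `PET = 0.0023 * Ra * (tas + 17.8) * sqrt(tasmax - tasmin)` (mm/day),
#' scaled by the days in each month, with `Ra` the extraterrestrial radiation
#' (expressed in mm/day of evaporation equivalent) for the 15th of the month.
#' Negative values (very cold cells) are clamped to 0; where the sun does not
#' rise (polar night) the radiation term, and hence PET, is 0.
#'
#' @param tas,tasmin,tasmax monthly mean / min / max temperature (degrees C):
#'   length-12 vectors or `12 x n` matrices.
#' @param lat latitude in degrees N (scalar or length n).
#' @return `12 x n` matrix of monthly PET (mm), non-negative.
#' @export
#' @examples
#' pet <- estimate_pet(rep(18, 12), rep(12, 12), rep(24, 12), lat = 45)
#' pet[7, ]
estimate_pet <- function(tas, tasmin, tasmax, lat) {
  tas <- as_month_matrix(tas); tasmin <- as_month_matrix(tasmin)
  tasmax <- as_month_matrix(tasmax)
  if (any(tasmax < tasmin)) stop("tasmax must be >= tasmin")
  n <- ncol(tas)
  lat <- rep_len(lat, n)
  ra <- extraterrestrial_radiation(lat)     # 12 x n, mm/day equivalent
  pet_day <- 0.0023 * ra * (tas + 17.8) * sqrt(tasmax - tasmin)
  pet_day <- pmax(pet_day, 0)
  pet_day * DAYS_IN_MONTH
}

# FAO-56 extraterrestrial radiation for the 15th of each month, converted to
# evaporation equivalent (mm/day): Ra_mm = 0.408 * Ra_MJ.
extraterrestrial_radiation <- function(lat) {
  J <- c(15, 46, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)
  phi <- lat * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * J / 365)
  delta <- 0.409 * sin(2 * pi * J / 365 - 1.39)
  # ws per (month, cell)
  x <- -outer(delta, tan(phi), function(d, tp) tan(d) * tp)
  # outer above multiplies tan(delta) by tan(phi); clamp for polar day/night
  x <- pmin(pmax(x, -1), 1)
  ws <- acos(x)
  ra <- (24 * 60 / pi) * 0.0820 * dr *
    (ws * outer(sin(delta), sin(phi)) + outer(cos(delta), cos(phi)) * sin(ws))
  0.408 * pmax(ra, 0)
}

# Accept a length-12 vector or a 12 x n matrix; always return 12 x n.
as_month_matrix <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) != 12) stop("monthly matrix must have 12 rows")
    return(x)
  }
  if (length(x) != 12) stop("monthly vector must have 12 values")
  matrix(x, nrow = 12)
}

#' Per-cell bioclimatic indices for one period
#'
#' Computes HI, CNI and DI for every grid cell of a [generate_climate()]
#' period (or any field list with `tasmin`/`tas`/`tasmax`/`pr` arrays of
#' shape `[12, rows, cols]`).
#'
#' @param climate a `climate_grids` object.
#' @param period period/scenario name in `climate$periods`.
#' @param di_parameters a [di_params()] object.
#' @param pet optional pre-computed PET (`12 x n_cells` matrix, cells in
#'   column-major grid order); overrides the Hargreaves estimate.
#' @return data.frame with `row`, `col`, `lat`, `hi`, `cni`, `di`,
#'   `tas_gs` (mean April-September temperature, used for the
#'   thermal-diversity diagnostic).
#' @export
bioclim_grid <- function(climate, period = "present",
                         di_parameters = di_params(), pet = NULL) {
  stopifnot(inherits(climate, "climate_grids"))
  if (!period %in% names(climate$periods)) {
    stop(sprintf("unknown period '%s'", period))
  }
  f <- climate$periods[[period]]
  nr <- climate$shape[1]; nc <- climate$shape[2]
  ncell <- nr * nc
  to_mat <- function(a) matrix(a, nrow = 12, ncol = ncell)  # [12, cells]
  tas <- to_mat(f$tas); tasmin <- to_mat(f$tasmin)
  tasmax <- to_mat(f$tasmax); pr <- to_mat(f$pr)
  cell_row <- rep(seq_len(nr), times = nc)
  cell_col <- rep(seq_len(nc), each = nr)
  lat <- climate$lat[cell_row]
  if (is.null(pet)) pet <- estimate_pet(tas, tasmin, tasmax, lat)
  data.frame(
    row = cell_row, col = cell_col, lat = lat,
    hi = huglin_index(tas, tasmax, lat),
    cni = cool_night_index(tasmin),
    di = dryness_index(pr, pet, di_parameters),
    tas_gs = colMeans(tas[GROWING_MONTHS, , drop = FALSE])
  )
}

#' Aggregate cell bioclimatic indices to regions
#'
#' Weighted mean of each index over a region's member cells (fractional
#' weights honoured), plus the within-region weighted SD of growing-season
#' mean temperature (`thermal_sd`, the spatial thermal-diversity diagnostic).
#'
#' @param grid_bioclim output of [bioclim_grid()].
#' @param regions a `region_set` (or any list with `cells` and `regions`
#'   data.frames as documented there).
#' @return data.frame: `region_id`, `hi`, `cni`, `di`, `thermal_sd`.
#' @export
regional_bioclim <- function(grid_bioclim, regions) {
  cells <- regions$cells
  check_columns(cells, c("region_id", "row", "col", "weight"), "regions$cells")
  if (!nrow(cells)) stop("region set has no member cells")
  key_grid <- paste(grid_bioclim$row, grid_bioclim$col)
  idx <- match(paste(cells$row, cells$col), key_grid)
  if (any(is.na(idx))) stop("region cells outside the bioclim grid")
  by_region <- split(seq_len(nrow(cells)), cells$region_id)
  out <- do.call(rbind, lapply(names(by_region), function(rid) {
    i <- by_region[[rid]]
    w <- cells$weight[i]
    if (sum(w) <= 0) stop(sprintf("region %s has zero total weight", rid))
    g <- grid_bioclim[idx[i], ]
    th <- weighted_moments(g$tas_gs, w)
    data.frame(region_id = rid,
               hi = sum(w * g$hi) / sum(w),
               cni = sum(w * g$cni) / sum(w),
               di = sum(w * g$di) / sum(w),
               thermal_sd = th$sd,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
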