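#' Generate monthly climatology grids for a present period and future scenarios
#'
#' Builds spatially smooth monthly fields of minimum / mean / maximum
#' temperature (degrees C) and precipitation (mm/month) on the configured
#' grid. Temperature decreases northwards and carries a smooth pseudo-terrain
#' anomaly plus cell-level noise; precipitation is wetter in the north with a
#' drier summer in the south. Each future scenario adds a warming field (mean
#' `warming` degrees C, optionally stronger in the south via
#' `warming_gradient`) and multiplies precipitation by its factor. For the
#' default scenario, `n_members >= 2` pseudo-GCM ensemble members are emitted
#' whose mean equals the scenario field exactly.
#'
#' @param config a [synth_config()] object.
#' @return an object of class `climate_grids`: list with `lat` (per row),
#'   `lon` (per column), `periods` (named list of variable arrays
#'   `[12, rows, cols]` for `tasmin`, `tas`, `tasmax`, `pr`), and `members`
#'   (per scenario, list of member field lists; empty if `n_members < 2`).
#' @export
#' @examples
#' clim <- generate_climate(synth_config(grid_shape = c(8, 10), n_regions = 3))
#' dim(clim$periods$present$tas)
generate_climate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  lat <- seq(config$lat_range[2], config$lat_range[1], length.out = nr)
  lon <- config$lon_origin + (seq_len(nc) - 0.5) * config$cell_size_deg
  months <- 1:12

  with_seed(derive_seed(config$seed, 101L), {
    terrain <- smooth_field(nr, nc)        # unit-SD smooth anomaly, deg C scale
    wetness <- smooth_field(nr, nc)        # smooth precipitation anomaly
    diurnal <- pmax(1.5, 4 + smooth_field(nr, nc))  # half of diurnal range

    lat_mat <- matrix(lat, nr, nc)
    southness <- (config$lat_range[2] - lat_mat) / diff(range(config$lat_range))
    annual_tas <- 17 - 0.55 * (lat_mat - config$lat_range[1]) + 1.5 * terrain

    mk_arr <- function() array(0, dim = c(12, nr, nc))
    tas <- mk_arr(); tasmin <- mk_arr(); tasmax <- mk_arr(); pr <- mk_arr()
    for (m in months) {
      seasonal <- 9 * cos(2 * pi * (m - 7) / 12)
      noise_t <- if (config$noise_sd > 0) {
        matrix(stats::rnorm(nr * nc, sd = config$noise_sd), nr, nc)
      } else matrix(0, nr, nc)
      noise_p <- if (config$noise_sd > 0) {
        matrix(stats::rnorm(nr * nc, sd = 4 * config$noise_sd), nr, nc)
      } else matrix(0, nr, nc)
      t_m <- annual_tas + seasonal + noise_t
      tas[m, , ] <- t_m
      tasmin[m, , ] <- t_m - diurnal
      tasmax[m, , ] <- t_m + diurnal
      p_m <- 70 + 25 * (1 - southness) + 12 * wetness -
        25 * southness * cos(2 * pi * (m - 7) / 12) + noise_p
      pr[m, , ] <- pmax(p_m, 0)
    }
    present <- list(tasmin = tasmin, tas = tas, tasmax = tasmax, pr = pr)

    # warming field: mean-preserving N-S modulation (stronger in the south)
    wmod <- 1 + config$warming_gradient * (southness - mean(southness))
    periods <- list(present = present)
    members <- list()
    for (sc in names(config$scenarios)) {
      spec <- config$scenarios[[sc]]
      dT <- spec$warming * wmod
      fnoise <- function() {
        if (config$future_noise_sd > 0) {
          array(stats::rnorm(12 * nr * nc, sd = config$future_noise_sd),
                dim = c(12, nr, nc))
        } else 0
      }
      add_dT <- function(a) sweep2(a, dT)
      fut <- list(
        tasmin = add_dT(present$tasmin) + fnoise(),
        tas = add_dT(present$tas) + fnoise(),
        tasmax = add_dT(present$tasmax) + fnoise(),
        pr = pmax(present$pr * spec$precip_factor + fnoise(), 0)
      )
      periods[[sc]] <- fut
      if (sc == config$default_scenario && config$n_members >= 2) {
        K <- config$n_members
        perturb <- lapply(seq_len(K), function(k) {
          matrix(stats::rnorm(nr * nc, sd = config$member_spread), nr, nc)
        })
        pbar <- Reduce(`+`, perturb) / K
        members[[sc]] <- lapply(seq_len(K), function(k) {
          d <- perturb[[k]] - pbar     # member offsets sum to zero exactly
          list(tasmin = sweep2(fut$tasmin, d), tas = sweep2(fut$tas, d),
               tasmax = sweep2(fut$tasmax, d), pr = pmax(sweep2(fut$pr, d), 0))
        })
        names(members[[sc]]) <- paste0("gcm", seq_len(K))
      }
    }
    structure(list(lat = lat, lon = lon, shape = c(nr, nc),
                   periods = periods, members = members,
                   config = config),
              class = "climate_grids")
  })
}

# add a (rows, cols) matrix to every month slice of a [12, rows, cols] array
sweep2 <- function(a, m) {
  if (identical(m, 0)) return(a)
  a + rep(m, each = 12)
}

#' @export
print.climate_grids <- function(x, ...) {
  cat(sprintf("monthly climatology grids: %d x %d cells, lat %.1f-%.1f N\n",
              x$shape[1], x$shape[2], min(x$lat), max(x$lat)))
  cat("  periods:", paste(names(x$periods), collapse = ", "), "\n")
  if (length(x$members)) {
    cat(sprintf("  ensemble members: %d (%s)\n",
                length(x$members[[1]]), names(x$members)[1]))
  }
  invisible(x)
}
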