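#' Generate contiguous winegrowing regions on the climate grid
#'
#' Places `n_regions` seed cells and grows disjoint contiguous blobs by
#' multi-source random accretion (4-neighbourhood) until each region reaches
#' its target size or runs out of free neighbours. Regions receive a country
#' label from coarse longitude/latitude blocks, a macro-region id (contiguous
#' chunks within a country, used for cultivation-area indirection) and a
#' log-normal vineyard area.
#'
#' @param config a [synth_config()] object.
#' @return an object of class `region_set`: list with `regions` (data.frame:
#'   `region_id`, `country`, `macro_id`, `centroid_lat`, `centroid_lon`,
#'   `vineyard_area_ha`, `n_cells`), `cells` (data.frame: `region_id`, `row`,
#'   `col`, `weight`; whole-cell membership has weight 1), `macro_map`
#'   (data.frame: `macro_id`, `region_id`) and the grid geometry.
#' @export
#' @examples
#' regs <- generate_regions(synth_config(grid_shape = c(10, 12), n_regions = 4))
#' nrow(regs$regions)
generate_regions <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  n <- config$n_regions
  if (n * config$region_size[1] > nr * nc) {
    stop("grid too small for the requested number of regions")
  }
  lat <- seq(config$lat_range[2], config$lat_range[1], length.out = nr)
  lon <- config$lon_origin + (seq_len(nc) - 0.5) * config$cell_size_deg

  with_seed(derive_seed(config$seed, 202L), {
    owner <- matrix(0L, nr, nc)
    seeds <- sample.int(nr * nc, n)
    owner[seeds] <- seq_len(n)
    size_choices <- seq(config$region_size[1], config$region_size[2])
    target <- size_choices[sample.int(length(size_choices), n, replace = TRUE)]
    size <- rep(1L, n)
    frontier <- lapply(seeds, function(s) s)  # linear indices per region
    active <- rep(TRUE, n)
    neigh <- function(idx) {
      r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
      out <- integer(0)
      if (r > 1L) out <- c(out, idx - 1L)
      if (r < nr) out <- c(out, idx + 1L)
      if (c > 1L) out <- c(out, idx - nr)
      if (c < nc) out <- c(out, idx + nr)
      out
    }
    while (any(active)) {
      progressed <- FALSE
      act <- which(active)
      for (i in act[sample.int(length(act))]) {
        if (size[i] >= target[i]) { active[i] <- FALSE; next }
        # free neighbours of the region's frontier
        cand <- unique(unlist(lapply(frontier[[i]], neigh)))
        cand <- cand[owner[cand] == 0L]
        if (!length(cand)) { active[i] <- FALSE; next }
        pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
        owner[pick] <- i
        frontier[[i]] <- c(frontier[[i]], pick)
        size[i] <- size[i] + 1L
        progressed <- TRUE
      }
      if (!progressed) break
    }

    cells <- which(owner > 0L, arr.ind = TRUE)
    cells_df <- data.frame(
      region_id = sprintf("R%03d", owner[owner > 0L]),
      row = cells[, 1], col = cells[, 2], weight = 1,
      stringsAsFactors = FALSE
    )
    cells_df <- cells_df[order(cells_df$region_id, cells_df$row, cells_df$col), ]
    rownames(cells_df) <- NULL

    cen_lat <- tapply(lat[cells_df$row], cells_df$region_id, mean)
    cen_lon <- tapply(lon[cells_df$col], cells_df$region_id, mean)
    ids <- sprintf("R%03d", seq_len(n))

    # coarse country blocks over the centroid cloud
    nb_lon <- max(1L, ceiling(sqrt(config$n_countries)))
    nb_lat <- max(1L, ceiling(config$n_countries / nb_lon))
    cut_idx <- function(v, k) {
      if (k == 1L) rep(1L, length(v)) else
        as.integer(cut(v, breaks = k, include.lowest = TRUE))
    }
    blk <- (cut_idx(cen_lat[ids], nb_lat) - 1L) * nb_lon + cut_idx(cen_lon[ids], nb_lon)
    country <- sprintf("C%02d", as.integer(factor(blk)))

    regions <- data.frame(
      region_id = ids, country = country,
      centroid_lat = as.numeric(cen_lat[ids]),
      centroid_lon = as.numeric(cen_lon[ids]),
      vineyard_area_ha = round(stats::rlnorm(n, log(1500), 0.6), 1),
      n_cells = as.integer(table(cells_df$region_id)[ids]),
      stringsAsFactors = FALSE
    )

    # macro units: contiguous longitude chunks within each country
    regions$macro_id <- NA_character_
    if (config$n_macro_regions > 0) {
      k_total <- config$n_macro_regions
      split_idx <- split(seq_len(n), regions$country)
      macro_count <- 0L
      for (grp in split_idx) {
        k_here <- max(1L, round(k_total * length(grp) / n))
        ord <- grp[order(regions$centroid_lon[grp])]
        chunk <- ceiling(seq_along(ord) / (length(ord) / k_here))
        regions$macro_id[ord] <- sprintf("M%02d", macro_count + chunk)
        macro_count <- macro_count + max(chunk)
      }
    }
    macro_map <- if (config$n_macro_regions > 0) {
      data.frame(macro_id = regions$macro_id, region_id = regions$region_id,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(macro_id = character(0), region_id = character(0))
    }

    structure(list(regions = regions, cells = cells_df, macro_map = macro_map,
                   lat = lat, lon = lon, shape = c(nr, nc),
                   cell_size_deg = config$cell_size_deg),
              class = "region_set")
  })
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region set: %d regions, %d cells, %d countries\n",
              nrow(x$regions), nrow(x$cells),
              length(unique(x$regions$country))))
  invisible(x)
}
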