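#' Write a complete synthetic fixture to disk
#'
#' Generates every pipeline input under one configuration and writes it in
#' the external interchange formats: long-format climate CSV (per period /
#' member), grid geometry CSV, regions as GeoJSON (cell-square
#' MultiPolygons) plus a cell-membership CSV, the variety catalog, synonym,
#' cultivation and macro-map CSVs, the indicator table with a YAML direction
#' sidecar, the expert AHP matrices, the ground-truth JSON and a manifest
#' with an MD5 hash per file. Identical configurations produce byte-identical
#' fixtures.
#'
#' @param config a [synth_config()] object.
#' @param out_dir writable output directory (created if needed).
#' @return invisibly, the manifest list (`files` with hashes, `config`).
#' @export
make_fixture <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_config"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir))
  clim <- generate_climate(config)
  regions <- generate_regions(config)
  var <- generate_varieties(config, regions, clim)
  ind <- generate_indicators(config, regions)
  ahp <- generate_ahp_matrices(config)

  path <- function(f) file.path(out_dir, f)
  written <- character(0)
  put_csv <- function(df, f) {
    data.table::fwrite(df, path(f))
    written <<- c(written, f)
  }

  # climate, long format
  clim_rows <- list()
  emit_fields <- function(fields, period, member) {
    nr <- clim$shape[1]; nc <- clim$shape[2]
    for (v in names(fields)) {
      a <- fields[[v]]
      clim_rows[[length(clim_rows) + 1L]] <<- data.table::data.table(
        period = period, member = member, variable = v,
        month = rep(1:12, times = nr * nc),
        row = rep(rep(seq_len(nr), each = 12), times = nc),
        col = rep(seq_len(nc), each = 12 * nr),
        value = round(as.vector(a), 4)
      )
    }
  }
  for (p in names(clim$periods)) emit_fields(clim$periods[[p]], p, "mean")
  for (sc in names(clim$members)) {
    for (mb in names(clim$members[[sc]])) {
      emit_fields(clim$members[[sc]][[mb]], sc, mb)
    }
  }
  put_csv(data.table::rbindlist(clim_rows), "climate.csv")
  put_csv(data.frame(row = rep(seq_along(clim$lat), times = length(clim$lon)),
                     col = rep(seq_along(clim$lon), each = length(clim$lat)),
                     lat = rep(clim$lat, times = length(clim$lon)),
                     lon = rep(clim$lon, each = length(clim$lat))),
          "grid.csv")

  writeLines(regions_geojson(regions), path("regions.geojson"))
  written <- c(written, "regions.geojson")
  put_csv(regions$cells, "region_cells.csv")
  put_csv(regions$regions, "regions.csv")
  put_csv(var$catalog, "varieties.csv")
  put_csv(var$synonyms, "synonyms.csv")
  put_csv(var$cultivation, "cultivation.csv")
  put_csv(var$macro_map, "macro_map.csv")
  put_csv(ind, "indicators.csv")
  yaml::write_yaml(as.list(attr(ind, "directions")), path("directions.yml"))
  written <- c(written, "directions.yml")
  for (e in seq_along(ahp$matrices)) {
    f <- sprintf("ahp_expert_%d.csv", e)
    utils::write.csv(round(ahp$matrices[[e]], 8), path(f))
    written <- c(written, f)
  }
  jsonlite::write_json(
    list(variety_optima = var$ground_truth$variety_optima,
         anchor_region = var$ground_truth$anchor_region,
         region_true_E_rank = var$ground_truth$region_true_E_rank,
         true_ac_weights = ahp$true_weights),
    path("ground_truth.json"), digits = 8, dataframe = "rows")
  written <- c(written, "ground_truth.json")

  manifest <- list(
    files = as.list(tools::md5sum(file.path(out_dir, sort(written)))),
    config = unclass(config)
  )
  names(manifest$files) <- sort(written)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = 8)
  invisible(manifest)
}

# GeoJSON FeatureCollection: one MultiPolygon of cell squares per region
regions_geojson <- function(regions) {
  lat <- regions$lat; lon <- regions$lon
  dlat <- if (length(lat) > 1) abs(lat[2] - lat[1]) / 2 else 0.125
  dlon <- regions$cell_size_deg / 2
  feats <- lapply(seq_len(nrow(regions$regions)), function(i) {
    r <- regions$regions[i, ]
    cc <- regions$cells[regions$cells$region_id == r$region_id, ]
    polys <- lapply(seq_len(nrow(cc)), function(j) {
      y <- lat[cc$row[j]]; x <- lon[cc$col[j]]
      ring <- list(c(x - dlon, y - dlat), c(x + dlon, y - dlat),
                   c(x + dlon, y + dlat), c(x - dlon, y + dlat),
                   c(x - dlon, y - dlat))
      list(lapply(ring, function(p) round(p, 6)))
    })
    list(type = "Feature",
         properties = list(region_id = r$region_id, country = r$country,
                           vineyard_area_ha = r$vineyard_area_ha),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                   auto_unbox = TRUE, digits = 8)
}

#' Read a fixture directory back into pipeline objects
#'
#' Inverse of [make_fixture()]: reconstructs the climate grids, region set,
#' variety tables, indicator table and ground truth from the interchange
#' files.
#'
#' @param dir fixture directory written by [make_fixture()].
#' @return list with `climate`, `regions`, `catalog`, `synonyms`,
#'   `cultivation`, `macro_map`, `indicators`, `ahp_matrices`,
#'   `ground_truth`, `manifest`.
#' @export
read_fixture <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop(sprintf("fixture file missing: %s", p))
    p
  }
  grid <- data.table::fread(need("grid.csv"), data.table = FALSE)
  lat <- grid$lat[match(seq_len(max(grid$row)), grid$row)]
  lon <- grid$lon[grid$row == 1][order(grid$col[grid$row == 1])]
  nr <- length(lat); nc <- length(lon)
  cl <- data.table::fread(need("climate.csv"), data.table = FALSE)
  to_fields <- function(d) {
    out <- list()
    for (v in unique(d$variable)) {
      dv <- d[d$variable == v, ]
      a <- array(0, dim = c(12, nr, nc))
      a[cbind(dv$month, dv$row, dv$col)] <- dv$value
      out[[v]] <- a
    }
    out
  }
  periods <- list(); members <- list()
  for (p in unique(cl$period)) {
    dp <- cl[cl$period == p, ]
    periods[[p]] <- to_fields(dp[dp$member == "mean", ])
    mb <- setdiff(unique(dp$member), "mean")
    if (length(mb)) {
      members[[p]] <- lapply(stats::setNames(mb, mb), function(m) {
        to_fields(dp[dp$member == m, ])
      })
    }
  }
  climate <- structure(list(lat = lat, lon = lon, shape = c(nr, nc),
                            periods = periods, members = members,
                            config = NULL),
                       class = "climate_grids")
  regs <- data.table::fread(need("regions.csv"), data.table = FALSE)
  cells <- data.table::fread(need("region_cells.csv"), data.table = FALSE)
  regions <- structure(list(regions = regs, cells = cells,
                            macro_map = data.table::fread(need("macro_map.csv"),
                                                          data.table = FALSE),
                            lat = lat, lon = lon, shape = c(nr, nc),
                            cell_size_deg = if (nc > 1) abs(lon[2] - lon[1]) else 0.25),
                       class = "region_set")
  ind <- data.table::fread(need("indicators.csv"), data.table = FALSE)
  dirs <- yaml::read_yaml(need("directions.yml"))
  attr(ind, "directions") <- unlist(dirs)
  ahp_files <- sort(list.files(dir, pattern = "^ahp_expert_\\d+\\.csv$"))
  ahp_matrices <- lapply(ahp_files, function(f) {
    m <- utils::read.csv(file.path(dir, f), row.names = 1, check.names = FALSE)
    as.matrix(m)
  })
  list(
    climate = climate, regions = regions,
    catalog = data.table::fread(need("varieties.csv"), data.table = FALSE),
    synonyms = data.table::fread(need("synonyms.csv"), data.table = FALSE,
                                 colClasses = "character"),
    cultivation = data.table::fread(need("cultivation.csv"),
                                    data.table = FALSE),
    macro_map = regions$macro_map,
    indicators = ind,
    ahp_matrices = ahp_matrices,
    ground_truth = jsonlite::read_json(need("ground_truth.json"),
                                       simplifyVector = TRUE),
    manifest = jsonlite::read_json(need("manifest.json"),
                                   simplifyVector = TRUE)
  )
}
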