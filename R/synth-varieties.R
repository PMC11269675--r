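#' Generate varieties, cultivation areas, synonyms and ground truth
#'
#' Each synthetic variety receives a true climatic optimum per bioclimatic
#' index (the present-day HI / CNI / DI of a randomly chosen anchor region).
#' Cultivation area is spread over regions with a Gaussian kernel in
#' standardized index distance from the optimum, so the area-weighted mean
#' of the cultivating regions' climates is a consistent estimator of the
#' optimum (the premise of the range-recovery tests). A configurable share
#' of cultivation rows is aggregated to macro-region level, and a fraction
#' of variety mentions is replaced by country-scoped aliases; most aliases
#' are recorded in the synonym table (split over a primary and a secondary
#' list), while a small `orphan_rate` fraction is left unmatched.
#'
#' @param config a [synth_config()] object.
#' @param regions a [generate_regions()] result.
#' @param climate a [generate_climate()] result (present period is used).
#' @return list with `catalog` (region_id, variety_name, country, role),
#'   `cultivation` (unit_id, unit_level, country, variety_name, area_ha),
#'   `synonyms` (canonical_name, synonym, country, list), `macro_map`, and
#'   `ground_truth` (list: `variety_optima` data.frame, `region_true_E_rank`,
#'   `anchor_region`).
#' @export
generate_varieties <- function(config, regions, climate) {
  stopifnot(inherits(config, "synth_config"), inherits(regions, "region_set"),
            inherits(climate, "climate_grids"))
  grid_b <- bioclim_grid(climate, "present")
  reg_b <- regional_bioclim(grid_b, regions)
  reg <- regions$regions
  n_v <- config$n_varieties

  with_seed(derive_seed(config$seed, 303L), {
    sds <- vapply(reg_b[c("hi", "cni", "di")], stats::sd, numeric(1))
    sds[!is.finite(sds) | sds == 0] <- 1
    anchors <- sample.int(nrow(reg_b), n_v, replace = n_v > nrow(reg_b))
    vnames <- sprintf("Variety%02d", seq_len(n_v))
    optima <- data.frame(variety = vnames,
                         hi = reg_b$hi[anchors],
                         cni = reg_b$cni[anchors],
                         di = reg_b$di[anchors],
                         stringsAsFactors = FALSE)

    # Gaussian kernel in standardized (HI, CNI, DI) distance from the optimum
    total_area <- stats::rlnorm(n_v, log(2500), 0.5)
    area <- matrix(0, nrow(reg_b), n_v, dimnames = list(reg_b$region_id, vnames))
    for (v in seq_len(n_v)) {
      d2 <- ((reg_b$hi - optima$hi[v]) / sds["hi"])^2 +
        ((reg_b$cni - optima$cni[v]) / sds["cni"])^2 +
        ((reg_b$di - optima$di[v]) / sds["di"])^2
      w <- exp(-0.5 * d2 / config$kernel_bw^2)
      w[w < 1e-6 * max(w)] <- 0
      area[, v] <- total_area[v] * w / sum(w)
    }
    # authorized set per region: varieties holding meaningful area there;
    # guarantee at least 3 (or all) per region
    catalog <- do.call(rbind, lapply(seq_len(nrow(reg_b)), function(r) {
      a <- area[r, ]
      keep <- which(a >= 0.01 * sum(a) & a > 0)
      if (length(keep) < min(3L, n_v)) {
        keep <- order(a, decreasing = TRUE)[seq_len(min(3L, n_v))]
      }
      ord <- keep[order(a[keep], decreasing = TRUE)]
      cum <- cumsum(a[ord]) / sum(a[ord])
      role <- ifelse(cum <= 0.8 | seq_along(ord) == 1, "primary", "additional")
      data.frame(region_id = reg_b$region_id[r],
                 variety_name = vnames[ord], role = role,
                 stringsAsFactors = FALSE)
    }))
    catalog$country <- reg$country[match(catalog$region_id, reg$region_id)]
    # a fraction of regions leave the primary/additional split unspecified
    unspec <- sample(unique(catalog$region_id),
                     size = round(0.2 * nrow(reg_b)))
    catalog$role[catalog$region_id %in% unspec] <- "authorized"
    # zero out area not in the authorized catalog so allocation conserves it
    auth_key <- paste(catalog$region_id, catalog$variety_name)
    for (v in seq_len(n_v)) {
      ok <- paste(reg_b$region_id, vnames[v]) %in% auth_key
      area[!ok, v] <- 0
    }

    # cultivation rows: per (variety, region), optionally folded to macro level
    cult <- do.call(rbind, lapply(seq_len(n_v), function(v) {
      rid <- reg_b$region_id[area[, v] > 0]
      if (!length(rid)) return(NULL)
      data.frame(region_id = rid, variety_name = vnames[v],
                 area_ha = area[area[, v] > 0, v], stringsAsFactors = FALSE)
    }))
    cult$macro_id <- reg$macro_id[match(cult$region_id, reg$region_id)]
    cult$country <- reg$country[match(cult$region_id, reg$region_id)]
    if (config$n_macro_regions > 0 && config$macro_share > 0) {
      grp_key <- paste(cult$variety_name, cult$macro_id)
      grp_ids <- unique(grp_key)
      to_macro <- grp_ids[stats::runif(length(grp_ids)) < config$macro_share]
      is_macro <- grp_key %in% to_macro & !is.na(cult$macro_id)
    } else is_macro <- rep(FALSE, nrow(cult))
    pdo_rows <- cult[!is_macro, ]
    pdo_part <- data.frame(unit_id = pdo_rows$region_id, unit_level = "pdo",
                           country = pdo_rows$country,
                           variety_name = pdo_rows$variety_name,
                           area_ha = pdo_rows$area_ha, stringsAsFactors = FALSE)
    macro_part <- if (any(is_macro)) {
      mc <- cult[is_macro, ]
      agg <- stats::aggregate(area_ha ~ macro_id + variety_name + country,
                              mc, sum)
      data.frame(unit_id = agg$macro_id, unit_level = "macro",
                 country = agg$country, variety_name = agg$variety_name,
                 area_ha = agg$area_ha, stringsAsFactors = FALSE)
    } else NULL
    cultivation <- rbind(pdo_part, macro_part)
    rownames(cultivation) <- NULL

    # country-scoped aliases; orphan aliases stay out of the synonym table
    synonyms <- NULL
    if (config$synonym_rate > 0) {
      mention <- stats::runif(nrow(cultivation)) < config$synonym_rate
      key <- unique(paste(cultivation$variety_name[mention],
                          cultivation$country[mention], sep = "\r"))
      if (length(key)) {
        parts <- do.call(rbind, strsplit(key, "\r", fixed = TRUE))
        alias <- data.frame(canonical_name = parts[, 1], country = parts[, 2],
                            stringsAsFactors = FALSE)
        alias$synonym <- paste0(alias$canonical_name, "-syn-", alias$country)
        # never orphan a region's largest-area variety: every region must
        # keep at least one matched primary mention for the sensitivity stage
        top_v <- vnames[max.col(area, ties.method = "first")]
        protected <- unique(paste(top_v, reg$country[match(reg_b$region_id,
                                                           reg$region_id)],
                                  sep = "\r"))
        alias$orphan <- stats::runif(nrow(alias)) < config$orphan_rate &
          !(paste(alias$canonical_name, alias$country, sep = "\r") %in%
              protected)
        alias$list <- ifelse(stats::runif(nrow(alias)) < 0.5,
                             "primary", "secondary")
        akey <- paste(cultivation$variety_name, cultivation$country, sep = "\r")
        hit <- mention & akey %in% key
        map <- match(akey, paste(alias$canonical_name, alias$country,
                                 sep = "\r"))
        cultivation$variety_name[hit] <- alias$synonym[map[hit]]
        synonyms <- alias[!alias$orphan,
                          c("canonical_name", "synonym", "country", "list")]
      }
    }
    if (is.null(synonyms)) {
      synonyms <- data.frame(canonical_name = character(0),
                             synonym = character(0), country = character(0),
                             list = character(0), stringsAsFactors = FALSE)
    }

    # ground truth: optima plus the true exposure ordering implied by the
    # warming field (southern regions warm more when warming_gradient > 0)
    south <- rank(-reg$centroid_lat, ties.method = "first")
    list(
      catalog = catalog[, c("region_id", "country", "variety_name", "role")],
      cultivation = cultivation,
      synonyms = synonyms,
      macro_map = regions$macro_map,
      ground_truth = list(
        variety_optima = optima,
        anchor_region = reg_b$region_id[anchors],
        region_true_E_rank = data.frame(region_id = reg$region_id,
                                        true_rank = south,
                                        stringsAsFactors = FALSE)
      )
    )
  })
}
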