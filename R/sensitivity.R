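#' Default bioclimatic class edges for the multicriteria climate grouping
#'
#' Class boundaries per index used to bin regions into combined climate
#' groups (Geoviticulture multicriteria-style classes): HI at 1500 / 1800 /
#' 2100 / 2400 / 3000 degree C . days, CNI at 12 / 14 / 18 degrees C, DI at
#' -100 / 50 / 150 mm. Bins are right-closed (a value exactly on an edge
#' falls in the lower class). The resulting group inventory is the set of
#' observed (HI, CNI, DI) class triples.
#'
#' @return named list of strictly increasing numeric edge vectors.
#' @export
climate_class_edges <- function() {
  list(hi = c(1500, 1800, 2100, 2400, 3000),
       cni = c(12, 14, 18),
       di = c(-100, 50, 150))
}

#' Assign regions to combined climate groups
#'
#' Bins each regional HI / CNI / DI value by the configured class edges and
#' concatenates the three class indices into a group label. Values outside
#' all bins are impossible by construction (terminal classes are open-ended).
#'
#' @param records data.frame with `region_id`, `hi`, `cni`, `di`.
#' @param edges list as returned by [climate_class_edges()].
#' @return `records` with added `group_id` (e.g. `"HI3.CN2.DI4"`).
#' @export
classify_climate_group <- function(records, edges = climate_class_edges()) {
  check_columns(records, c("region_id", "hi", "cni", "di"), "records")
  for (e in edges) {
    if (is.unsorted(e, strictly = TRUE)) stop("class edges must be strictly increasing")
  }
  # right-closed bins: value == edge goes to the lower class
  bin <- function(x, e) findInterval(x, e, left.open = TRUE) + 1L
  records$group_id <- sprintf("HI%d.CN%d.DI%d",
                              bin(records$hi, edges$hi),
                              bin(records$cni, edges$cni),
                              bin(records$di, edges$di))
  records
}

#' Canonicalize variety names through country-scoped synonym lists
#'
#' Two-tier lookup: each (name, country) is first matched against the
#' primary synonym list, then the secondary list; names absent from both are
#' kept verbatim and flagged unmatched. Conflicting synonym targets within a
#' country are an error.
#'
#' @param x data.frame with columns `variety_name` and `country`.
#' @param synonyms data.frame with `canonical_name`, `synonym`, `country`
#'   and optionally `list` (`"primary"` / `"secondary"`, default primary).
#' @param known optional character vector of names that are already
#'   canonical (e.g. the catalog's variety inventory); defaults to the
#'   synonym table's canonical targets.
#' @return list: `data` (`x` with added `variety` = canonical name and
#'   logical `matched`; a name resolved through the synonym lists or already
#'   present in `known` counts as matched) and `report`
#'   (`matched_fraction`, `n_unmatched`, `unmatched` names).
#' @export
#' @examples
#' syn <- data.frame(canonical_name = "Pinot Noir",
#'                   synonym = "Spatburgunder", country = "DE")
#' canonicalize_varieties(
#'   data.frame(variety_name = "Spatburgunder", country = "DE"), syn
#' )$data$variety
canonicalize_varieties <- function(x, synonyms, known = NULL) {
  check_columns(x, c("variety_name", "country"), "x")
  if (is.null(synonyms) || !nrow(synonyms)) {
    synonyms <- data.frame(canonical_name = character(0),
                           synonym = character(0), country = character(0),
                           list = character(0), stringsAsFactors = FALSE)
  }
  check_columns(synonyms, c("canonical_name", "synonym", "country"), "synonyms")
  if (is.null(synonyms$list)) synonyms$list <- "primary"
  key <- paste(synonyms$country, synonyms$synonym, synonyms$list, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(synonyms$synonym[duplicated(key)])
    conf <- synonyms[synonyms$synonym %in% dup, ]
    tgt <- tapply(conf$canonical_name, paste(conf$country, conf$synonym),
                  function(v) length(unique(v)))
    if (any(tgt > 1)) {
      stop("conflicting synonym targets within a country: ",
           paste(names(tgt)[tgt > 1], collapse = "; "))
    }
    synonyms <- synonyms[!duplicated(key), ]
  }
  lookup <- function(tier, names_vec, country_vec) {
    tab <- synonyms[synonyms$list == tier, ]
    i <- match(paste(country_vec, names_vec, sep = "\r"),
               paste(tab$country, tab$synonym, sep = "\r"))
    tab$canonical_name[i]
  }
  canon <- lookup("primary", x$variety_name, x$country)
  sec <- lookup("secondary", x$variety_name, x$country)
  canon[is.na(canon)] <- sec[is.na(canon)]
  # a name that is itself canonical needs no mapping
  if (is.null(known)) known <- synonyms$canonical_name
  is_known <- x$variety_name %in% known
  matched <- !is.na(canon) | is_known
  out <- x
  out$variety <- ifelse(is.na(canon), x$variety_name, canon)
  out$matched <- matched
  list(data = out,
       report = list(
         matched_fraction = if (nrow(x)) mean(matched) else 1,
         n_unmatched = sum(!matched),
         unmatched = sort(unique(x$variety_name[!matched]))
       ))
}

#' Resolve the primary-variety set of each region
#'
#' Regions with at least one explicitly primary variety keep only those as
#' primary; regions whose roles are all unspecified (`"authorized"` or `NA`)
#' have every authorized variety promoted to primary.
#'
#' @param catalog data.frame with `region_id`, `variety`, `role` in
#'   `{"primary", "additional", "authorized", NA}`.
#' @return the catalog with `role` resolved to `"primary"`/`"additional"`.
#' @export
resolve_primary <- function(catalog) {
  check_columns(catalog, c("region_id", "variety", "role"), "catalog")
  if (!nrow(catalog)) stop("empty variety catalog")
  empty <- setdiff(unique(catalog$region_id),
                   catalog$region_id[!is.na(catalog$variety)])
  if (length(empty)) {
    stop("region(s) with empty variety list: ", paste(empty, collapse = ", "))
  }
  role <- as.character(catalog$role)
  unspecified <- is.na(role) | role == "authorized"
  has_primary <- tapply(role == "primary" & !unspecified, catalog$region_id,
                        any)
  promote <- !has_primary[catalog$region_id]
  role[unspecified & promote] <- "primary"
  role[unspecified & !promote] <- "additional"
  catalog$role <- role
  catalog
}

#' Allocate cultivation areas to regions
#'
#' Region-level (`pdo`) rows pass through; macro-level rows are split among
#' the macro's member regions that authorize the variety, proportionally to
#' their vineyard area, so the split conserves the macro total. Varieties
#' authorized nowhere in their macro-region are dropped with a warning.
#' Unmatched variety names (not in any region's catalog anywhere) are also
#' dropped and counted.
#'
#' @param cultivation data.frame: `unit_id`, `unit_level` (`"pdo"`/`"macro"`),
#'   `variety`, `area_ha`.
#' @param macro_map data.frame: `macro_id`, `region_id`.
#' @param regions data.frame with `region_id`, `vineyard_area_ha`.
#' @param catalog resolved variety catalog (`region_id`, `variety`, `role`).
#' @return data.frame `region_id`, `variety`, `area_ha` (summed over rows),
#'   with attribute `dropped` (data.frame of dropped rows and reasons).
#' @export
allocate_cultivation <- function(cultivation, macro_map, regions, catalog) {
  check_columns(cultivation, c("unit_id", "unit_level", "variety", "area_ha"),
                "cultivation")
  check_columns(regions, c("region_id", "vineyard_area_ha"), "regions")
  check_columns(catalog, c("region_id", "variety"), "catalog")
  if (any(cultivation$area_ha < 0)) stop("negative cultivation area")
  auth_key <- paste(catalog$region_id, catalog$variety)
  rows <- list(); dropped <- list()
  for (i in seq_len(nrow(cultivation))) {
    rec <- cultivation[i, ]
    if (rec$unit_level == "pdo") {
      if (!paste(rec$unit_id, rec$variety) %in% auth_key) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(unit_id = rec$unit_id, variety = rec$variety,
                     area_ha = rec$area_ha, reason = "not authorized",
                     stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(region_id = rec$unit_id, variety = rec$variety,
                   area_ha = rec$area_ha, stringsAsFactors = FALSE)
    } else if (rec$unit_level == "macro") {
      member <- macro_map$region_id[macro_map$macro_id == rec$unit_id]
      if (!length(member)) stop(sprintf("macro id '%s' not in macro_map",
                                        rec$unit_id))
      member <- member[paste(member, rec$variety) %in% auth_key]
      if (!length(member)) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(unit_id = rec$unit_id, variety = rec$variety,
                     area_ha = rec$area_ha,
                     reason = "no authorizing member region",
                     stringsAsFactors = FALSE)
        next
      }
      va <- regions$vineyard_area_ha[match(member, regions$region_id)]
      if (any(is.na(va))) stop("macro member region missing vineyard area")
      if (sum(va) <= 0) {
        stop(sprintf("macro '%s': zero total vineyard area among authorizing members",
                     rec$unit_id))
      }
      rows[[length(rows) + 1L]] <-
        data.frame(region_id = member, variety = rec$variety,
                   area_ha = rec$area_ha * va / sum(va),
                   stringsAsFactors = FALSE)
    } else {
      stop(sprintf("unknown unit_level '%s'", rec$unit_level))
    }
  }
  alloc <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region_id = character(0), variety = character(0),
               area_ha = numeric(0))
  if (nrow(alloc)) {
    agg <- stats::aggregate(area_ha ~ region_id + variety, alloc, sum)
  } else agg <- alloc
  drp <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(unit_id = character(0), variety = character(0),
               area_ha = numeric(0), reason = character(0))
  if (nrow(drp)) {
    warning(sprintf("dropped %d cultivation row(s) with no authorizing region",
                    nrow(drp)))
  }
  attr(agg, "dropped") <- drp
  agg
}

#' Bioregional climate ranges per variety and climate group
#'
#' For every (variety, climate group) with positive cultivation area:
#' the cultivation-area-weighted mean and frequency-weighted (population
#' style) SD of each bioclimatic index across the cultivating regions, and
#' the upper range limit `mean + sd_multiplier * sd`. A single cultivating
#' region gives SD 0 and an upper limit equal to the mean.
#'
#' @param regional data.frame from [regional_bioclim()] (present period),
#'   with `group_id` added by [classify_climate_group()].
#' @param allocation data.frame from [allocate_cultivation()].
#' @param sd_multiplier width of the range in weighted SDs (default 1).
#' @return data.frame: `variety`, `group_id`, `index` (hi/cni/di),
#'   `weighted_mean`, `weighted_sd`, `upper_limit`, `total_area`.
#' @export
estimate_ranges <- function(regional, allocation, sd_multiplier = 1) {
  check_columns(regional, c("region_id", "hi", "cni", "di", "group_id"),
                "regional")
  check_columns(allocation, c("region_id", "variety", "area_ha"), "allocation")
  i <- match(allocation$region_id, regional$region_id)
  if (any(is.na(i))) {
    stop("allocation region(s) without a bioclim record: ",
         paste(unique(allocation$region_id[is.na(i)]), collapse = ", "))
  }
  dat <- cbind(allocation, regional[i, c("hi", "cni", "di", "group_id")])
  dat <- dat[dat$area_ha > 0, ]
  groups <- split(dat, list(dat$variety, dat$group_id), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(c("hi", "cni", "di"), function(ix) {
      wm <- weighted_moments(g[[ix]], g$area_ha)
      data.frame(variety = g$variety[1], group_id = g$group_id[1],
                 index = ix, weighted_mean = wm$mean, weighted_sd = wm$sd,
                 upper_limit = wm$mean + sd_multiplier * wm$sd,
                 total_area = sum(g$area_ha), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out[order(out$variety, out$group_id, out$index), ]
}

#' Regional sensitivity from upper-range margins
#'
#' For each (region, primary variety) pair: the margin of each index is the
#' variety's upper range limit (in the region's climate group) minus the
#' region's current value. Margins are standardized per index across all
#' pairs (default: z-score), averaged over the three indices, negated (a
#' small or negative margin means high sensitivity), averaged over the
#' region's primary varieties weighted by cultivation area, and finally
#' min-max scaled across regions to [0, 1].
#'
#' @param regional present-period regional bioclim with `group_id`.
#' @param ranges data.frame from [estimate_ranges()].
#' @param allocation data.frame from [allocate_cultivation()].
#' @param catalog resolved catalog; only `role == "primary"` pairs count.
#' @param standardize `"zscore"` (default), `"minmax"` or `"raw"` margin
#'   standardization strategy.
#' @return data.frame: `region_id`, `sensitivity` in [0, 1].
#' @export
gi_sensitivity <- function(regional, ranges, allocation, catalog,
                           standardize = c("zscore", "minmax", "raw")) {
  standardize <- match.arg(standardize)
  check_columns(regional, c("region_id", "hi", "cni", "di", "group_id"),
                "regional")
  pairs <- build_pairs(regional, ranges, allocation, catalog)
  if (!nrow(pairs)) stop("no (region, primary variety) pair has a range")
  miss <- setdiff(regional$region_id, pairs$region_id)
  if (length(miss)) {
    stop("region(s) with no primary variety in any range: ",
         paste(miss, collapse = ", "))
  }
  for (ix in c("hi", "cni", "di")) {
    m <- pairs[[paste0("margin_", ix)]]
    z <- switch(standardize,
                zscore = if (stats::sd(m) > 0) (m - mean(m)) / stats::sd(m) else m * 0,
                minmax = minmax_scale(m),
                raw = m)
    pairs[[paste0("z_", ix)]] <- z
  }
  pairs$score <- -(pairs$z_hi + pairs$z_cni + pairs$z_di) / 3
  agg <- vapply(split(pairs, pairs$region_id), function(g) {
    sum(g$score * g$area_ha) / sum(g$area_ha)
  }, numeric(1))
  out <- data.frame(region_id = names(agg), raw_score = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out$sensitivity <- minmax_scale(out$raw_score)
  out[match(regional$region_id, out$region_id), c("region_id", "sensitivity")]
}

# join allocation x primary catalog x region group x ranges into margin pairs
build_pairs <- function(regional, ranges, allocation, catalog) {
  check_columns(ranges, c("variety", "group_id", "index", "weighted_mean",
                          "weighted_sd", "upper_limit"), "ranges")
  check_columns(allocation, c("region_id", "variety", "area_ha"), "allocation")
  check_columns(catalog, c("region_id", "variety", "role"), "catalog")
  prim <- catalog[catalog$role == "primary", ]
  a <- allocation[paste(allocation$region_id, allocation$variety) %in%
                    paste(prim$region_id, prim$variety) &
                    allocation$area_ha > 0, ]
  if (!nrow(a)) {
    return(data.frame(region_id = character(0), variety = character(0),
                      area_ha = numeric(0)))
  }
  ri <- match(a$region_id, regional$region_id)
  a$group_id <- regional$group_id[ri]
  wide <- function(ix, col) {
    r <- ranges[ranges$index == ix, ]
    r[[col]][match(paste(a$variety, a$group_id), paste(r$variety, r$group_id))]
  }
  for (ix in c("hi", "cni", "di")) {
    a[[paste0("upper_", ix)]] <- wide(ix, "upper_limit")
    a[[paste0("ref_", ix)]] <- wide(ix, "weighted_mean")
    a[[paste0("margin_", ix)]] <- a[[paste0("upper_", ix)]] - regional[[ix]][ri]
    a[[paste0("cur_", ix)]] <- regional[[ix]][ri]
  }
  a <- a[!is.na(a$upper_hi), ]  # pairs whose variety has no range in the group
  a
}

#' Share of primary varieties with potential positive climate-change effects
#'
#' Uses each variety's group-wise weighted mean as its reference. A variety
#' benefits in a region if its mean (over the three indices) absolute
#' standardized deviation from the reference is strictly smaller under the
#' future than under the present conditions; ties count as not benefiting.
#' Deviations are standardized per index by the SD of present-day regional
#' values so that HI, CNI and DI are commensurable. The regional share is
#' the cultivation-area-weighted (default) or plain fraction of benefiting
#' primary varieties.
#'
#' @param regional_present,regional_future regional bioclim records (the
#'   present one with `group_id`; future values are compared against the
#'   same present-day references).
#' @param ranges,allocation,catalog as in [gi_sensitivity()].
#' @param rule `"mean_abs"` (default) or `"majority"` (a variety benefits if
#'   it moves closer to the reference on at least two of three indices).
#' @param weighting `"area"` (default) or `"count"`.
#' @return data.frame: `region_id`, `positive_share` in [0, 1].
#' @export
positive_effect_share <- function(regional_present, regional_future,
                                  ranges, allocation, catalog,
                                  rule = c("mean_abs", "majority"),
                                  weighting = c("area", "count")) {
  rule <- match.arg(rule); weighting <- match.arg(weighting)
  check_columns(regional_future, c("region_id", "hi", "cni", "di"),
                "regional_future")
  miss <- setdiff(regional_present$region_id, regional_future$region_id)
  if (length(miss)) {
    stop("missing future record for region(s): ", paste(miss, collapse = ", "))
  }
  pairs <- build_pairs(regional_present, ranges, allocation, catalog)
  if (!nrow(pairs)) stop("no (region, primary variety) pair has a range")
  fi <- match(pairs$region_id, regional_future$region_id)
  scale_sd <- vapply(c("hi", "cni", "di"), function(ix) {
    s <- stats::sd(regional_present[[ix]])
    if (!is.finite(s) || s == 0) 1 else s
  }, numeric(1))
  dev <- function(values_by_ix) {
    d <- mapply(function(ix, v) {
      abs(v - pairs[[paste0("ref_", ix)]]) / scale_sd[[ix]]
    }, c("hi", "cni", "di"),
    values_by_ix, SIMPLIFY = FALSE)
    d
  }
  dev_pres <- dev(lapply(c("hi", "cni", "di"),
                         function(ix) pairs[[paste0("cur_", ix)]]))
  dev_fut <- dev(lapply(c("hi", "cni", "di"),
                        function(ix) regional_future[[ix]][fi]))
  if (rule == "mean_abs") {
    benefits <- (Reduce(`+`, dev_fut) / 3) < (Reduce(`+`, dev_pres) / 3)
  } else {
    closer <- mapply(function(f, p) f < p, dev_fut, dev_pres)
    benefits <- rowSums(matrix(closer, ncol = 3)) >= 2
  }
  w <- if (weighting == "area") pairs$area_ha else rep(1, nrow(pairs))
  agg <- vapply(split(seq_len(nrow(pairs)), pairs$region_id), function(i) {
    sum(w[i] * benefits[i]) / sum(w[i])
  }, numeric(1))
  out <- data.frame(region_id = names(agg), positive_share = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out[match(regional_present$region_id, out$region_id), ]
}
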