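#' Run the integrated vulnerability assessment end-to-end
#'
#' Orchestrates every stage on synthetic inputs (or a fixture directory):
#' bioclimatic indices per period, regional aggregation, exposure from
#' adverse index deltas, variety canonicalization and cultivation-area
#' allocation, bioregional climate ranges, regional sensitivity and
#' positive-effect shares per scenario, the adaptive-capacity composite,
#' AHP analysis of the expert matrices, and the final vulnerability
#' classification. All tabular results are returned; with `out_dir` they
#' are also written as CSV/JSON together with a manifest (file hashes,
#' stage log, warning counts). Identical configurations produce
#' byte-identical outputs.
#'
#' @param config a [synth_config()] object, or a path to a fixture
#'   directory written by [make_fixture()].
#' @param out_dir optional output directory.
#' @param scenario future scenario used for exposure and sensitivity
#'   (default `"ssp370"`).
#' @param exposure_mode `"signed"` or `"absolute"` delta handling.
#' @param standardize sensitivity margin standardization strategy.
#' @param benefit_rule positive-effect rule (`"mean_abs"` / `"majority"`).
#' @param weighting_mode `"equal"` (main analysis) or `"ahp"` (mean of the
#'   accepted experts' AHP weights).
#' @return invisibly, a list with all stage outputs: `regional_bioclim`
#'   (per period), `exposure`, `ranges`, `sensitivity`, `positive_share`
#'   (per scenario), `capacity`, `ahp_report`, `profiles`,
#'   `country_summary`, `match_report`, `manifest`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(synth_config(grid_shape = c(12, 15), n_regions = 6,
#'                                  n_varieties = 6, seed = 7))
#' head(res$profiles)
#' }
run_pipeline <- function(config, out_dir = NULL, scenario = "ssp370",
                         exposure_mode = c("signed", "absolute"),
                         standardize = c("zscore", "minmax", "raw"),
                         benefit_rule = c("mean_abs", "majority"),
                         weighting_mode = c("equal", "ahp")) {
  exposure_mode <- match.arg(exposure_mode)
  standardize <- match.arg(standardize)
  benefit_rule <- match.arg(benefit_rule)
  weighting_mode <- match.arg(weighting_mode)
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message("[vitivuln] ", msg)
  }

  if (is.character(config)) {
    say("loading fixture from %s", config)
    fx <- read_fixture(config)
    climate <- fx$climate; regions <- fx$regions
    catalog_raw <- fx$catalog; synonyms <- fx$synonyms
    cultivation_raw <- fx$cultivation; indicators <- fx$indicators
    ahp_matrices <- fx$ahp_matrices
  } else if (inherits(config, "synth_config")) {
    say("simulating inputs (seed %d)", config$seed)
    climate <- generate_climate(config)
    regions <- generate_regions(config)
    var <- generate_varieties(config, regions, climate)
    catalog_raw <- var$catalog
    synonyms <- var$synonyms
    cultivation_raw <- var$cultivation
    indicators <- generate_indicators(config, regions)
    ahp_matrices <- generate_ahp_matrices(config)$matrices
  } else {
    stop("config must be a synth_config or a fixture directory path")
  }
  if (!scenario %in% names(climate$periods)) {
    stop(sprintf("scenario '%s' not among periods (%s)", scenario,
                 paste(names(climate$periods), collapse = ", ")))
  }

  # --- bioclim ---------------------------------------------------------
  reg_bio <- lapply(stats::setNames(nm = names(climate$periods)), function(p) {
    regional_bioclim(bioclim_grid(climate, p), regions)
  })
  say("bioclim: %d regions x %d periods", nrow(reg_bio$present),
      length(reg_bio))

  # --- exposure --------------------------------------------------------
  deltas <- adverse_delta(reg_bio$present, reg_bio[[scenario]])
  exposure <- exposure_index(deltas, mode = exposure_mode)
  say("exposure: scenario %s, mean %.3f", scenario, mean(exposure$exposure))

  # --- varieties / sensitivity ----------------------------------------
  catalog <- catalog_raw
  names(catalog)[names(catalog) == "variety_name"] <- "variety"
  catalog <- resolve_primary(catalog)
  canon <- canonicalize_varieties(cultivation_raw, synonyms,
                                  known = unique(catalog$variety))
  match_report <- canon$report
  say("variety matching: %.1f%% of %d cultivation mentions matched",
      100 * match_report$matched_fraction, nrow(cultivation_raw))
  cult <- canon$data[canon$data$matched, ]
  n_dropped_unmatched <- sum(!canon$data$matched)
  alloc <- withCallingHandlers(
    allocate_cultivation(
      data.frame(unit_id = cult$unit_id, unit_level = cult$unit_level,
                 variety = cult$variety, area_ha = cult$area_ha,
                 stringsAsFactors = FALSE),
      regions$macro_map, regions$regions, catalog),
    warning = function(w) invokeRestart("muffleWarning"))
  n_dropped_alloc <- nrow(attr(alloc, "dropped"))
  say("allocation: %d (region, variety) pairs, %d rows dropped",
      nrow(alloc), n_dropped_alloc)

  present_grp <- classify_climate_group(reg_bio$present)
  ranges <- estimate_ranges(present_grp, alloc)
  say("ranges: %d varieties x %d climate groups",
      length(unique(ranges$variety)), length(unique(ranges$group_id)))
  sens <- gi_sensitivity(present_grp, ranges, alloc, catalog,
                         standardize = standardize)
  scen_names <- setdiff(names(climate$periods), "present")
  pos <- lapply(stats::setNames(nm = scen_names), function(sc) {
    positive_effect_share(present_grp, reg_bio[[sc]], ranges, alloc,
                          catalog, rule = benefit_rule)
  })
  say("sensitivity: mean %.3f; positive share (%s): %s",
      mean(sens$sensitivity), paste(scen_names, collapse = "/"),
      paste(sprintf("%.2f", vapply(pos, function(p) mean(p$positive_share),
                                   numeric(1))), collapse = "/"))

  # --- adaptive capacity ----------------------------------------------
  scaled <- scale_indicators(indicators)
  n_degenerate <- attr(scaled, "n_degenerate")
  ahp_report <- lapply(seq_along(ahp_matrices), function(e) {
    r <- ahp_weights(ahp_matrices[[e]])
    list(expert = e, weights = as.numeric(r$weights),
         lambda_max = r$lambda_max, cr = r$cr,
         accepted = isTRUE(check_consistency(r$cr)))
  })
  weights <- NULL
  if (weighting_mode == "ahp") {
    acc <- Filter(function(r) r$accepted, ahp_report)
    if (!length(acc)) stop("no AHP matrix passes the CR < 0.10 gate")
    weights <- colMeans(do.call(rbind, lapply(acc, `[[`, "weights")))
    names(weights) <- setdiff(names(scaled), "region_id")
  }
  capacity <- aggregate_capacity(scaled, weights = weights)
  say("capacity: mean AC %.3f (%s weights), %d/%d AHP matrices consistent",
      mean(capacity$ac), weighting_mode,
      sum(vapply(ahp_report, `[[`, logical(1), "accepted")),
      length(ahp_report))

  # --- vulnerability ---------------------------------------------------
  vul <- assemble_profiles(exposure[, c("region_id", "exposure")], sens,
                           capacity[, c("region_id", "ac")],
                           regions = regions$regions)
  say("vulnerability: %s",
      paste(sprintf("%s=%d", levels(vul$profiles$level),
                    as.integer(table(vul$profiles$level))), collapse = ", "))

  result <- list(
    regional_bioclim = reg_bio, exposure = exposure, allocation = alloc,
    ranges = ranges, sensitivity = sens, positive_share = pos,
    capacity = capacity, ahp_report = ahp_report,
    profiles = vul$profiles, country_summary = vul$country_summary,
    match_report = match_report,
    warnings = list(n_unmatched_mentions = n_dropped_unmatched,
                    n_dropped_allocations = n_dropped_alloc,
                    n_degenerate_columns = n_degenerate),
    log = log
  )

  if (!is.null(out_dir)) {
    result$manifest <- write_outputs(result, out_dir, scenario,
                                     list(exposure_mode = exposure_mode,
                                          standardize = standardize,
                                          benefit_rule = benefit_rule,
                                          weighting_mode = weighting_mode))
  }
  invisible(result)
}

write_outputs <- function(result, out_dir, scenario, options) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir))
  written <- character(0)
  put <- function(df, f) {
    data.table::fwrite(round_numeric(df), file.path(out_dir, f))
    written <<- c(written, f)
  }
  bio <- do.call(rbind, lapply(names(result$regional_bioclim), function(p) {
    cbind(period = p, result$regional_bioclim[[p]])
  }))
  put(bio, "bioclim_regions.csv")
  put(result$exposure, "exposure.csv")
  put(result$ranges, "ranges.csv")
  sens <- result$sensitivity
  for (sc in names(result$positive_share)) {
    sens[[paste0("positive_share_", sc)]] <-
      result$positive_share[[sc]]$positive_share
  }
  put(sens, "sensitivity.csv")
  put(result$capacity, "capacity.csv")
  put(result$profiles, "vulnerability.csv")
  if (!is.null(result$country_summary)) {
    put(result$country_summary, "country_summary.csv")
  }
  jsonlite::write_json(result$ahp_report, file.path(out_dir, "ahp_report.json"),
                       auto_unbox = TRUE, digits = 8)
  jsonlite::write_json(result$match_report,
                       file.path(out_dir, "match_report.json"),
                       auto_unbox = TRUE, digits = 8)
  written <- c(written, "ahp_report.json", "match_report.json")
  manifest <- list(
    scenario = scenario, options = options,
    stage_log = result$log, warnings = result$warnings,
    files = as.list(tools::md5sum(file.path(out_dir, sort(written))))
  )
  names(manifest$files) <- sort(written)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 8)
  manifest
}

# stable CSV output: round numerics to avoid platform-dependent last digits
round_numeric <- function(df) {
  df <- as.data.frame(df)
  for (i in seq_along(df)) {
    if (is.numeric(df[[i]])) df[[i]] <- round(df[[i]], 8)
    if (is.factor(df[[i]])) df[[i]] <- as.character(df[[i]])
  }
  df
}
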