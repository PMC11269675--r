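#' Tertile classification of a score across regions
#'
#' Cuts at the 33rd and 66th percentiles (linear interpolation): values at
#' or below the lower cut are `low`, at or below the upper cut `moderate`,
#' above it `high`. Ties on a cut resolve downward; if all values are equal
#' both cuts coincide and every region is `low`.
#'
#' @param values numeric scores, one per region (>= 3 values).
#' @return factor with levels `low`, `moderate`, `high`.
#' @export
#' @examples
#' table(tertile_classes(1:9))
tertile_classes <- function(values) {
  if (length(values) < 3) stop("tertile classification needs >= 3 regions")
  if (any(!is.finite(values))) stop("non-finite scores")
  q <- stats::quantile(values, probs = c(0.33, 0.66), names = FALSE, type = 7)
  cls <- ifelse(values <= q[1], "low",
                ifelse(values <= q[2], "moderate", "high"))
  factor(cls, levels = c("low", "moderate", "high"))
}

#' Vulnerability level from tertile classes
#'
#' Adverse conditions are high exposure, high sensitivity, low adaptive
#' capacity; favorable conditions are their opposites. Precedence:
#' all three adverse gives `very_high`; exactly two adverse gives `high`;
#' otherwise at least two favorable gives `low`; everything else is
#' `moderate`.
#'
#' @param e_class,s_class,ac_class tertile classes (`low` / `moderate` /
#'   `high`), vectorized.
#' @return factor with levels `low`, `moderate`, `high`, `very_high`.
#' @export
#' @examples
#' vulnerability_level("high", "high", "low")
vulnerability_level <- function(e_class, s_class, ac_class) {
  e_class <- as.character(e_class); s_class <- as.character(s_class)
  ac_class <- as.character(ac_class)
  check_class_values(e_class, s_class, ac_class)
  n_adv <- (e_class == "high") + (s_class == "high") + (ac_class == "low")
  n_fav <- (e_class == "low") + (s_class == "low") + (ac_class == "high")
  lvl <- ifelse(n_adv == 3, "very_high",
                ifelse(n_adv == 2, "high",
                       ifelse(n_fav >= 2, "low", "moderate")))
  factor(lvl, levels = c("low", "moderate", "high", "very_high"))
}

#' Vulnerability group (1-6) from tertile classes
#'
#' Group 6 is the very-high level; within the high level the adverse pair
#' decides: exposure + sensitivity -> group 3, exposure + low capacity ->
#' group 4, sensitivity + low capacity -> group 5. The moderate level is
#' group 2 and the low level group 1.
#'
#' @inheritParams vulnerability_level
#' @return integer group in 1..6.
#' @export
#' @examples
#' vulnerability_group("high", "low", "low")
vulnerability_group <- function(e_class, s_class, ac_class) {
  e_class <- as.character(e_class); s_class <- as.character(s_class)
  ac_class <- as.character(ac_class)
  lvl <- as.character(vulnerability_level(e_class, s_class, ac_class))
  grp <- integer(length(lvl))
  grp[lvl == "very_high"] <- 6L
  grp[lvl == "moderate"] <- 2L
  grp[lvl == "low"] <- 1L
  hi <- lvl == "high"
  grp[hi & e_class == "high" & s_class == "high"] <- 3L
  grp[hi & e_class == "high" & ac_class == "low"] <- 4L
  grp[hi & s_class == "high" & ac_class == "low"] <- 5L
  grp
}

check_class_values <- function(...) {
  v <- unlist(list(...))
  bad <- setdiff(unique(v), c("low", "moderate", "high"))
  if (length(bad)) stop("invalid tertile class: ", paste(bad, collapse = ", "))
  lens <- vapply(list(...), length, integer(1))
  if (length(unique(lens)) != 1) stop("class vectors differ in length")
  invisible(NULL)
}

#' Assemble the integrated vulnerability profiles
#'
#' Joins the exposure, sensitivity and adaptive-capacity tables over an
#' identical region set, derives the tertile classes, the vulnerability
#' level and the group of every region, and summarizes level shares per
#' country when a region table with countries is supplied.
#'
#' @param exposure data.frame with `region_id`, `exposure`.
#' @param sensitivity data.frame with `region_id`, `sensitivity`.
#' @param capacity data.frame with `region_id`, `ac`.
#' @param regions optional data.frame with `region_id`, `country`.
#' @return list: `profiles` (region_id, the three scores, `e_class`,
#'   `s_class`, `ac_class`, `level`, `group`) and `country_summary`
#'   (`country`, `level`, `percent`; percentages sum to 100 per country;
#'   NULL without a region table).
#' @export
assemble_profiles <- function(exposure, sensitivity, capacity,
                              regions = NULL) {
  check_columns(exposure, c("region_id", "exposure"), "exposure")
  check_columns(sensitivity, c("region_id", "sensitivity"), "sensitivity")
  check_columns(capacity, c("region_id", "ac"), "capacity")
  ids <- exposure$region_id
  for (nm in c("sensitivity", "capacity")) {
    other <- get(nm)$region_id
    if (!setequal(ids, other) || length(ids) != length(other)) {
      miss <- c(setdiff(ids, other), setdiff(other, ids))
      stop(sprintf("region sets differ between exposure and %s: %s", nm,
                   paste(unique(miss), collapse = ", ")))
    }
  }
  prof <- data.frame(
    region_id = ids,
    exposure = exposure$exposure,
    sensitivity = sensitivity$sensitivity[match(ids, sensitivity$region_id)],
    ac = capacity$ac[match(ids, capacity$region_id)],
    stringsAsFactors = FALSE
  )
  prof$e_class <- tertile_classes(prof$exposure)
  prof$s_class <- tertile_classes(prof$sensitivity)
  prof$ac_class <- tertile_classes(prof$ac)
  prof$level <- vulnerability_level(prof$e_class, prof$s_class, prof$ac_class)
  prof$group <- vulnerability_group(prof$e_class, prof$s_class, prof$ac_class)

  country_summary <- NULL
  if (!is.null(regions)) {
    check_columns(regions, c("region_id", "country"), "regions")
    prof$country <- regions$country[match(prof$region_id, regions$region_id)]
    tab <- table(prof$country, prof$level)
    pct <- prop.table(tab, margin = 1) * 100
    country_summary <- as.data.frame(pct, stringsAsFactors = FALSE)
    names(country_summary) <- c("country", "level", "percent")
  }
  list(profiles = prof, country_summary = country_summary)
}
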