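test_that("synonym homogenization is country-scoped and two-tier", {
  syn <- data.frame(canonical_name = c("Pinot Noir", "Garnacha"),
                    synonym = c("Spatburgunder", "Grenache"),
                    country = c("DE", "ES"),
                    list = c("primary", "secondary"))
  x <- data.frame(variety_name = c("Spatburgunder", "Grenache",
                                   "Spatburgunder", "Mystery"),
                  country = c("DE", "ES", "FR", "DE"))
  out <- canonicalize_varieties(x, syn)
  expect_equal(out$data$variety,
               c("Pinot Noir", "Garnacha", "Spatburgunder", "Mystery"))
  # country scoping: the FR mention of a DE synonym stays unmatched
  expect_equal(out$data$matched, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$report$matched_fraction, 0.5)
  expect_setequal(out$report$unmatched, c("Spatburgunder", "Mystery"))
})

test_that("primary list wins over secondary and conflicts are an error", {
  syn <- data.frame(canonical_name = c("A-prim", "A-sec"),
                    synonym = c("Alias", "Alias"), country = c("X", "X"),
                    list = c("primary", "secondary"))
  out <- canonicalize_varieties(
    data.frame(variety_name = "Alias", country = "X"), syn)
  expect_equal(out$data$variety, "A-prim")
  conf <- data.frame(canonical_name = c("A", "B"), synonym = c("S", "S"),
                     country = c("X", "X"), list = c("primary", "primary"))
  expect_error(canonicalize_varieties(
    data.frame(variety_name = "S", country = "X"), conf), "conflict")
})

test_that("an unaliased fixture matches every cultivation mention", {
  cfg <- small_config(synonym_rate = 0)
  regs <- generate_regions(cfg)
  v <- generate_varieties(cfg, regs, generate_climate(cfg))
  out <- canonicalize_varieties(v$cultivation, v$synonyms,
                                known = unique(v$catalog$variety_name))
  expect_equal(out$report$matched_fraction, 1)
})

test_that("primary resolution keeps explicit splits and promotes unspecified", {
  cat <- data.frame(
    region_id = c("A", "A", "B", "B", "C"),
    variety = c("v1", "v2", "v3", "v4", "v5"),
    role = c("primary", "additional", "authorized", "authorized", NA)
  )
  out <- resolve_primary(cat)
  expect_equal(out$role, c("primary", "additional", "primary", "primary",
                           "primary"))
  expect_error(resolve_primary(cat[0, ]), "empty")
})

test_that("cultivation allocation splits macro rows by vineyard area", {
  regions <- data.frame(region_id = c("R1", "R2", "R3"),
                        vineyard_area_ha = c(100, 300, 50))
  macro_map <- data.frame(macro_id = c("M1", "M1", "M1"),
                          region_id = c("R1", "R2", "R3"))
  catalog <- data.frame(region_id = c("R1", "R2", "R1"),
                        variety = c("v", "v", "w"),
                        role = "primary")
  cult <- data.frame(unit_id = "M1", unit_level = "macro", variety = "v",
                     area_ha = 400)
  a <- allocate_cultivation(cult, macro_map, regions, catalog)
  expect_equal(a$area_ha[match(c("R1", "R2"), a$region_id)], c(100, 300))
  expect_equal(sum(a$area_ha), 400)   # conservation
  # single authorizing member takes everything
  cult_w <- data.frame(unit_id = "M1", unit_level = "macro", variety = "w",
                       area_ha = 400)
  aw <- allocate_cultivation(cult_w, macro_map, regions, catalog)
  expect_equal(aw$area_ha, 400)
  expect_equal(aw$region_id, "R1")
  # pdo rows pass through
  pdo <- data.frame(unit_id = "R2", unit_level = "pdo", variety = "v",
                    area_ha = 55)
  expect_equal(allocate_cultivation(pdo, macro_map, regions, catalog)$area_ha,
               55)
  # a variety authorized nowhere in the macro drops with a warning
  cult_x <- data.frame(unit_id = "M1", unit_level = "macro", variety = "x",
                       area_ha = 10)
  expect_warning(ax <- allocate_cultivation(cult_x, macro_map, regions,
                                            catalog), "dropped")
  expect_equal(nrow(ax), 0)
  expect_equal(nrow(attr(ax, "dropped")), 1)
  # zero total vineyard area among authorizers is an error
  regions0 <- transform(regions, vineyard_area_ha = 0)
  expect_error(allocate_cultivation(cult, macro_map, regions0, catalog),
               "zero total vineyard area")
})

test_that("allocation conserves macro totals on the synthetic fixture", {
  w <- small_world()
  catalog <- w$var$catalog
  names(catalog)[names(catalog) == "variety_name"] <- "variety"
  catalog <- resolve_primary(catalog)
  cult <- w$var$cultivation
  names(cult)[names(cult) == "variety_name"] <- "variety"
  a <- suppressWarnings(
    allocate_cultivation(cult[, c("unit_id", "unit_level", "variety",
                                  "area_ha")],
                         w$regs$macro_map, w$regs$regions, catalog))
  dropped <- attr(a, "dropped")
  expect_equal(sum(a$area_ha) + sum(dropped$area_ha), sum(cult$area_ha),
               tolerance = 1e-6)
})

test_that("climate grouping bins by right-closed edges deterministically", {
  rec <- data.frame(region_id = c("A", "B", "C", "D"),
                    hi = c(1200, 1500, 1501, 3200),
                    cni = c(11, 12, 12.5, 19),
                    di = c(160, 150, 60, -120))
  g <- classify_climate_group(rec)
  expect_equal(g$group_id[1], "HI1.CN1.DI4")     # coolest HI class
  expect_equal(g$group_id[2], "HI1.CN1.DI3")     # on-edge values fall low
  expect_equal(g$group_id[3], "HI2.CN2.DI3")
  expect_equal(g$group_id[4], "HI6.CN4.DI1")
  # identical bins give identical groups
  twin <- classify_climate_group(data.frame(region_id = "E", hi = 1499,
                                            cni = 11.5, di = 155))
  expect_equal(twin$group_id, g$group_id[1])
  expect_error(classify_climate_group(rec, list(hi = c(2, 1), cni = 1,
                                                di = 1)), "increasing")
})

test_that("bioregional ranges match hand-computed weighted moments", {
  grp <- data.frame(region_id = c("R1", "R2"), hi = c(1800, 2000),
                    cni = c(12, 12), di = c(100, 100),
                    group_id = "G1")
  alloc <- data.frame(region_id = c("R1", "R2"), variety = "v",
                      area_ha = c(100, 300))
  rng <- estimate_ranges(grp, alloc)
  hi <- rng[rng$index == "hi", ]
  expect_equal(hi$weighted_mean, 1950)
  expect_equal(hi$weighted_sd, 86.60, tolerance = 0.005)
  expect_equal(hi$upper_limit, 2036.60, tolerance = 0.005)
  expect_equal(hi$total_area, 400)
  # equal areas reduce to the unweighted population moments
  alloc_eq <- transform(alloc, area_ha = 50)
  hi_eq <- estimate_ranges(grp, alloc_eq)
  hi_eq <- hi_eq[hi_eq$index == "hi", ]
  expect_equal(hi_eq$weighted_mean, mean(c(1800, 2000)))
  expect_equal(hi_eq$weighted_sd,
               sqrt(mean((c(1800, 2000) - 1900)^2)))
  # sd multiplier widens the upper limit
  wide <- estimate_ranges(grp, alloc, sd_multiplier = 2)
  expect_equal(wide[wide$index == "hi", "upper_limit"],
               1950 + 2 * hi$weighted_sd)
})

test_that("sensitivity ranks regions by margin and honours area weights", {
  # two regions, single variety each, margins differing only in HI
  grp <- data.frame(region_id = c("R1", "R2"), hi = c(1950, 1800),
                    cni = c(12, 12), di = c(100, 100), group_id = "G1")
  alloc <- data.frame(region_id = c("R1", "R2"), variety = c("a", "b"),
                      area_ha = c(100, 100))
  catalog <- data.frame(region_id = c("R1", "R2"), variety = c("a", "b"),
                        role = "primary")
  ranges <- expand.grid(variety = c("a", "b"), index = c("hi", "cni", "di"),
                        stringsAsFactors = FALSE)
  ranges$group_id <- "G1"
  ranges$weighted_mean <- ifelse(ranges$index == "hi", 1900, 100)
  ranges$weighted_sd <- 0
  ranges$upper_limit <- ifelse(ranges$index == "hi", 2000,
                               ifelse(ranges$index == "cni", 12, 100))
  # margins: R1 hi 50, R2 hi 200; cni/di margins equal across regions
  s <- gi_sensitivity(grp, ranges, alloc, catalog)
  expect_equal(s$sensitivity[s$region_id == "R1"], 1)
  expect_equal(s$sensitivity[s$region_id == "R2"], 0)

  # area weighting: shifting area to the low-margin variety raises the score
  grp1 <- data.frame(region_id = "R1", hi = 1950, cni = 12, di = 100,
                     group_id = "G1")
  al2 <- data.frame(region_id = c("R1", "R1"), variety = c("a", "b"),
                    area_ha = c(1, 1))
  cat2 <- data.frame(region_id = c("R1", "R1"), variety = c("a", "b"),
                     role = "primary")
  rng2 <- ranges
  rng2$upper_limit <- ifelse(rng2$variety == "a" & rng2$index == "hi", 1960,
                             ifelse(rng2$index == "hi", 2200,
                                    rng2$upper_limit))
  pair_score <- function(areas) {
    al <- transform(al2, area_ha = areas)
    p <- vitivuln:::build_pairs(grp1, rng2, al, cat2)
    sum(p$area_ha * -p$margin_hi) / sum(p$area_ha)
  }
  expect_gt(pair_score(c(3, 1)), pair_score(c(1, 3)))
})

test_that("enlarging all upper limits never increases sensitivity", {
  res <- study_pipeline()
  bio <- study_bioclim()
  present_grp <- classify_climate_group(bio$present)
  # recompute with widened ranges
  rngs <- res$ranges
  rngs_wide <- transform(rngs, upper_limit = upper_limit + 30)
  cat_full <- cached("study_catalog", {
    cfg <- study_config()
    v <- generate_varieties(cfg, generate_regions(cfg),
                            generate_climate(cfg))
    cc <- v$catalog
    names(cc)[names(cc) == "variety_name"] <- "variety"
    resolve_primary(cc)
  })
  s1 <- gi_sensitivity(present_grp, rngs, res$allocation, cat_full)
  s2 <- gi_sensitivity(present_grp, rngs_wide, res$allocation, cat_full)
  # uniform widening shifts all margins equally: z-scores, and hence the
  # scaled sensitivity, are unchanged -- anti-monotonicity shows as no rise
  expect_true(all(s2$sensitivity <= s1$sensitivity + 1e-9))
})

test_that("positive-effect shares follow the deviation comparison and tie rule", {
  grp <- data.frame(region_id = "R1", hi = 1800, cni = 12, di = 100,
                    group_id = "G1")
  fut_same <- grp[, c("region_id", "hi", "cni", "di")]
  alloc <- data.frame(region_id = "R1", variety = "v", area_ha = 10)
  catalog <- data.frame(region_id = "R1", variety = "v", role = "primary")
  ranges <- data.frame(variety = "v", group_id = "G1",
                       index = c("hi", "cni", "di"),
                       weighted_mean = c(2000, 12, 100), weighted_sd = 0,
                       upper_limit = c(2000, 12, 100), total_area = 10)
  # future identical to present: ties count as not benefiting
  p0 <- positive_effect_share(grp, fut_same, ranges, alloc, catalog)
  expect_equal(p0$positive_share, 0)
  # present HI 200 below the reference, future only 50 below: benefits
  fut_better <- transform(fut_same, hi = 1950)
  p1 <- positive_effect_share(grp, fut_better, ranges, alloc, catalog)
  expect_equal(p1$positive_share, 1)
  expect_error(positive_effect_share(grp, fut_same[0, ], ranges, alloc,
                                     catalog), "missing future")
})

test_that("positive share is non-increasing along the warming ladder", {
  res <- study_pipeline()
  shares <- vapply(res$positive_share[c("ssp126", "ssp370", "ssp585")],
                   function(p) mean(p$positive_share), numeric(1))
  expect_true(all(diff(shares) <= 1e-12))
  for (p in res$positive_share) {
    expect_true(all(p$positive_share >= 0 & p$positive_share <= 1))
  }
})
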