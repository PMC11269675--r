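test_that("config validation rejects impossible settings", {
  expect_error(synth_config(grid_shape = c(0, 10)), "grid_shape")
  expect_error(synth_config(grid_shape = c(-4, 10)), "grid_shape")
  expect_error(synth_config(synonym_rate = 1.2), "synonym_rate")
  expect_error(synth_config(n_regions = 2), "n_regions")
  expect_error(synth_config(indicator_corr = 1), "indicator_corr")
  expect_error(synth_config(indicator_corr = -0.5), "indicator_corr")
  expect_error(synth_config(grid_shape = c(3, 3), n_regions = 20),
               "too small")
})

test_that("zero-change scenario reproduces the present fields exactly", {
  cfg <- synth_config(grid_shape = c(8, 10), n_regions = 3,
                      warming_delta_C = 0, precip_factor = 1, noise_sd = 0,
                      n_members = 0, seed = 5)
  clim <- generate_climate(cfg)
  for (sc in c("ssp126", "ssp370", "ssp585")) {
    for (v in c("tasmin", "tas", "tasmax", "pr")) {
      expect_identical(clim$periods[[sc]][[v]], clim$periods$present[[v]])
    }
  }
})

test_that("uniform warming adds exactly the configured delta", {
  cfg <- synth_config(grid_shape = c(8, 10), n_regions = 3,
                      warming_delta_C = 2, warming_gradient = 0,
                      noise_sd = 0, n_members = 0, seed = 5)
  clim <- generate_climate(cfg)
  d <- clim$periods$ssp370$tas - clim$periods$present$tas
  expect_true(all(abs(d - 2) < 1e-12))
})

test_that("climate generation is deterministic and physically consistent", {
  cfg <- synth_config(grid_shape = c(10, 12), n_regions = 4, seed = 7)
  a <- generate_climate(cfg)
  b <- generate_climate(cfg)
  expect_identical(a, b)
  for (p in names(a$periods)) {
    f <- a$periods[[p]]
    expect_true(all(f$tasmin <= f$tas + 1e-12))
    expect_true(all(f$tas <= f$tasmax + 1e-12))
    expect_true(all(f$pr >= 0))
  }
})

test_that("pseudo-GCM members average exactly to the scenario field", {
  cfg <- synth_config(grid_shape = c(8, 10), n_regions = 3, n_members = 4,
                      seed = 9)
  clim <- generate_climate(cfg)
  mem <- clim$members$ssp370
  expect_length(mem, 4)
  avg <- Reduce(`+`, lapply(mem, `[[`, "tas")) / 4
  expect_equal(avg, clim$periods$ssp370$tas, tolerance = 1e-12)
})

test_that("regions are disjoint, contiguous blobs covering every region", {
  w <- small_world()
  cells <- w$regs$cells
  expect_false(anyDuplicated(paste(cells$row, cells$col)) > 0)
  expect_setequal(unique(cells$region_id), w$regs$regions$region_id)
  expect_true(all(w$regs$regions$n_cells >= 1))
  expect_true(all(w$regs$regions$vineyard_area_ha > 0))
  # contiguity: every region's cells form one 4-connected component
  for (rid in unique(cells$region_id)) {
    cc <- cells[cells$region_id == rid, ]
    seen <- 1L
    frontier <- 1L
    repeat {
      nb <- which(!seq_len(nrow(cc)) %in% seen &
                    sapply(seq_len(nrow(cc)), function(i) {
                      any(abs(cc$row[i] - cc$row[seen]) +
                            abs(cc$col[i] - cc$col[seen]) == 1)
                    }))
      if (!length(nb)) break
      seen <- c(seen, nb)
    }
    expect_length(seen, nrow(cc))
  }
})

test_that("region generation honours seed and weight normalization", {
  cfg <- synth_config(grid_shape = c(10, 10), n_regions = 3, seed = 3)
  a <- generate_regions(cfg)
  b <- generate_regions(cfg)
  expect_identical(a$cells, b$cells)
  one <- generate_regions(synth_config(grid_shape = c(6, 6), n_regions = 3,
                                       seed = 1))
  w <- tapply(one$cells$weight, one$cells$region_id, function(x) x / sum(x))
  for (ws in w) expect_equal(sum(ws), 1)
})

test_that("variety generator honours aliasing and macro switches", {
  w <- small_world()
  cfg0 <- small_config(synonym_rate = 0)
  v0 <- generate_varieties(cfg0, w$regs, w$clim)
  expect_true(all(v0$cultivation$variety_name %in% v0$catalog$variety_name))
  expect_equal(nrow(v0$synonyms), 0)

  cfg_nm <- small_config(n_macro_regions = 0)
  regs_nm <- generate_regions(cfg_nm)
  vm <- generate_varieties(cfg_nm, regs_nm, generate_climate(cfg_nm))
  expect_true(all(vm$cultivation$unit_level == "pdo"))

  # ground truth persisted: one optimum per variety per index
  gt <- w$var$ground_truth$variety_optima
  expect_equal(nrow(gt), w$cfg$n_varieties)
  expect_true(all(c("hi", "cni", "di") %in% names(gt)))
})

test_that("a variety cultivated in a single region recovers that region's climate", {
  w <- small_world()
  reg_b <- regional_bioclim(bioclim_grid(w$clim, "present"), w$regs)
  grp <- classify_climate_group(reg_b)
  rid <- reg_b$region_id[1]
  alloc <- data.frame(region_id = rid, variety = "Solo", area_ha = 120)
  rng <- estimate_ranges(grp, alloc)
  hi_row <- rng[rng$index == "hi", ]
  expect_equal(hi_row$weighted_mean, reg_b$hi[1])
  expect_equal(hi_row$weighted_sd, 0)
  expect_equal(hi_row$upper_limit, hi_row$weighted_mean)
})

test_that("indicator table is deterministic with near-target correlation", {
  cfg <- synth_config(n_regions = 300, indicator_corr = 0, seed = 13)
  a <- generate_indicators(cfg, 300)
  b <- generate_indicators(cfg, 300)
  expect_identical(a, b)
  cors <- stats::cor(as.matrix(a[, -1]))
  off <- cors[upper.tri(cors)]
  expect_lt(max(abs(off)), 0.25)   # target 0 at n = 300
  expect_length(attr(a, "directions"), 15)
  expect_error(generate_indicators(synth_config(indicator_corr = 0.99),
                                   "not a count"), "region_set|count")
})

test_that("fixture round-trips byte-identically and completely", {
  cfg <- synth_config(grid_shape = c(10, 12), n_regions = 4, n_varieties = 4,
                      n_members = 2, seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- make_fixture(cfg, d1)
  m2 <- make_fixture(cfg, d2)
  expect_identical(unname(unlist(m1$files)), unname(unlist(m2$files)))
  expect_true(all(c("climate.csv", "regions.geojson", "varieties.csv",
                    "synonyms.csv", "cultivation.csv", "macro_map.csv",
                    "indicators.csv", "ground_truth.json")
                  %in% names(m1$files)))
  fx <- read_fixture(d1)
  expect_s3_class(fx$climate, "climate_grids")
  expect_equal(nrow(fx$regions$regions), 4)
  expect_equal(nrow(fx$ground_truth$variety_optima), 4)
  # GeoJSON parses and covers all regions
  gj <- jsonlite::read_json(file.path(d1, "regions.geojson"))
  expect_equal(length(gj$features), 4)
})

test_that("a minimal fixture drives the pipeline end-to-end", {
  cfg <- synth_config(grid_shape = c(10, 12), n_regions = 3, n_varieties = 2,
                      n_macro_regions = 1, synonym_rate = 0.5, seed = 33)
  d <- withr::local_tempdir()
  make_fixture(cfg, d)
  res <- suppressMessages(run_pipeline(d, out_dir = file.path(d, "out")))
  expect_equal(nrow(res$profiles), 3)
  expect_true(file.exists(file.path(d, "out", "vulnerability.csv")))
})
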