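# Shared fixtures, built once per test run and cached in the helper env.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small, fast configuration for unit tests
small_config <- function(...) {
  args <- list(grid_shape = c(16, 20), n_regions = 12, n_varieties = 8,
               n_macro_regions = 3, seed = 42)
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}

small_world <- function() {
  cached("small_world", {
    cfg <- small_config()
    clim <- generate_climate(cfg)
    regs <- generate_regions(cfg)
    list(cfg = cfg, clim = clim, regs = regs,
         var = generate_varieties(cfg, regs, clim))
  })
}

# the 200-region study-scale fixture used by the recovery and monotonicity
# checks: low field noise, spatially uniform warming
study_config <- function() {
  synth_config(n_regions = 200, n_varieties = 30, noise_sd = 0.1,
               warming_gradient = 0, seed = 7)
}

study_pipeline <- function() {
  cached("study_pipeline", {
    suppressMessages(run_pipeline(study_config()))
  })
}

# regional bioclim records per period for the study fixture
study_bioclim <- function() {
  cached("study_bioclim", study_pipeline()$regional_bioclim)
}
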