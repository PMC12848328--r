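# Expensive solver runs shared across test files, computed once per test
# session.  testthat sources helpers once and runs files alphabetically, so
# test-acceptance.R (first) triggers most of these.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# canonical coarse-grid 5-cycle sweep (the study conditions)
cached_sweep <- function() {
  cached("sweep", {
    cfg <- storage_config()
    simulate_sweep(cfg, c(0, 20, 40, 60))
  })
}

cached_sweep_analysis <- function() {
  cached("sweep_analysis", analyze_runs(cached_sweep(), storage_config()))
}

# small fast forced run for structural tests
cached_small_run <- function() {
  cached("small20", {
    run_simulation(protocol = agitation_protocol(0.02, 20, 2L),
                   grid = grid_spec(48, 16))
  })
}

# same conditions with dense snapshots, for field-interpolation tests
cached_dense_run <- function() {
  cached("small20_dense", {
    run_simulation(protocol = agitation_protocol(0.02, 20, 2L),
                   grid = grid_spec(48, 16),
                   snapshot_norm_times = seq(0.025, 1, by = 0.025))
  })
}
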