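# Small simulated datasets shared across test files, built once per run.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# 40 default-scenario 50 kb regions with a modest sample, reused by
# feature, simulation and diagnostics tests.
small_regions <- function() {
  cached("small_regions",
         simulate_regions(demography(), n_rep = 40, n_target = 20,
                          n_ref = 20, n_archaic = 1, seed = 424242))
}
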