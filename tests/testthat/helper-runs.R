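# Shared simulation runs, cached across test files so the acceptance and
# property tests reuse the same replicates instead of re-simulating.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(scenario, origin, seed, steps = 20000L, ...) {
  key <- paste(scenario, origin, seed, steps, sep = "_")
  if (is.null(.run_cache[[key]])) {
    cfg <- scenario_preset(scenario, origin, seed = as.integer(seed),
                           max_steps = as.integer(steps), ...)
    .run_cache[[key]] <- run_simulation(cfg)
  }
  .run_cache[[key]]
}

# replicate seeds used throughout the acceptance suite
ACC_SEEDS <- c(11L, 12L, 13L)

# equilibrium summary: median of a snapshot column over the second half of
# the run (per-region columns give a median profile)
equilibrium_median <- function(res, cols) {
  s <- res$snapshots
  s <- s[s$time > max(s$time) / 2, , drop = FALSE]
  vapply(cols, function(cl) stats::median(s[[cl]], na.rm = TRUE), numeric(1))
}
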