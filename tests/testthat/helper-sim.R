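# Shared default simulation, built once per test run (seed fixed a priori).
sim_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(sim_cache$sim)) {
    sim_cache$sim <- simulate_study(simulation_config(seed = 2026))
  }
  sim_cache$sim
}

default_report <- function() {
  if (is.null(sim_cache$report)) {
    sim <- default_sim()
    sim_cache$report <- run_pipeline(sim$inputs, seed = 2026,
                                     params = list(n_iter = 99, n_sets = 500))
  }
  sim_cache$report
}
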