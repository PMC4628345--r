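# Expensive shared computations, run at most once per test session.

cached_battery <- function() {
  if (is.null(.fixtures$sa)) {
    t0 <- Sys.time()
    .fixtures$sa <- run_scenarios(test_params())
    .fixtures$sa_elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  }
  .fixtures$sa
}

battery_elapsed <- function() {
  cached_battery()
  .fixtures$sa_elapsed
}

cached_base_run <- function() {
  if (is.null(.fixtures$base_run)) {
    .fixtures$base_run <- run_cea(test_params(), keep_trajectories = TRUE)
  }
  .fixtures$base_run
}

scenario_icer <- function(name) {
  sa <- cached_battery()
  sa$icer[sa$scenario == name]
}
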