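# Shared simulated genome / survey, computed once per test run.

.sim_cache <- new.env()

default_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_genome(seed = 101)
  }
  .sim_cache$sim
}

default_survey <- function() {
  if (is.null(.sim_cache$survey)) {
    sim <- default_sim()
    .sim_cache$survey <- suppressMessages(
      survey_p450s(sim$proteins, sim$cds, sim$models, sim$references))
  }
  .sim_cache$survey
}
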