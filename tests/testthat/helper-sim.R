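# A shared default-configuration simulation, generated once per test run.
# Several tests exercise the same "study conditions" dataset; memoising it
# keeps the suite fast without sharing state between assertions.
.sim_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    cfg <- sim_config(seed = 20)
    nests <- simulate_landscape(cfg)
    events <- simulate_breeding_seasons(nests, cfg)
    chicks <- simulate_chicks(events, cfg)
    .sim_cache$sim <- list(cfg = cfg, nests = nests, events = events,
                           chicks = chicks)
  }
  .sim_cache$sim
}

# Family-unit occurrence report on the default events (fitted once).
default_family_report <- function() {
  if (is.null(.sim_cache$family_report))
    .sim_cache$family_report <- run_family_unit_analysis(default_sim()$events)
  .sim_cache$family_report
}

# Encounter histories for the survival recovery checks: 2,000 chicks over 10
# occasions under the default configuration.
default_histories <- function() {
  if (is.null(.sim_cache$histories)) {
    sim <- default_sim()
    set.seed(21)
    idx <- sample(nrow(sim$chicks), 2000)
    .sim_cache$histories <- simulate_encounter_histories(
      sim$chicks[idx, ], sim$cfg, n_occasions = 10)
  }
  .sim_cache$histories
}
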