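## shared simulated fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

## the study-condition cohort: 352 persons, 44 items, ~7% aberrant
default_cohort <- function(seed = 11) {
  fixture(paste0("default", seed), function()
    simulate_cohort(simulation_config(seed = seed)))
}

## a cohort whose 8 domains carry independent traits (clear 8-factor
## structure), no aberrant responders
domain_cohort <- function() {
  fixture("domains", function()
    simulate_cohort(simulation_config(n_persons = 352, trait_sd = 0.3,
                                      domain_sd = 1, noise_sd = 0.5,
                                      aberrant_fraction = 0, seed = 3)))
}

default_model <- function() {
  fixture("model11", function() elmh_model(default_cohort()$responses))
}
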