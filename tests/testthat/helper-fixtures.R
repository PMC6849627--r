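# Shared, lazily computed fixtures.  Everything is generated in code under
# fixed seeds; expensive simulator states are cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# a bog spun up for 1200 years to 1750, used by scenario and pipeline tests
spun_state <- function() {
  fixture("spun_state", {
    spin <- gen_climate(1200, seed = 3, start_year = 551)
    simulate_peatland(spin)$state
  })
}

# shared 1751-2012 climate continuation
management_climate <- function() {
  fixture("management_climate", gen_climate(262, seed = 4, start_year = 1751))
}

run_scenario <- function(name) {
  fixture(paste0("run_", name), {
    simulate_peatland(management_climate(), schedule = scenario_preset(name),
                      init = spun_state())
  })
}

# small WA-Tol training set shared across transfer-function tests
training_fixture <- function() {
  fixture("training", gen_training_set(n_samples = 40, count_total = 150, seed = 11))
}

tf_fixture <- function() {
  fixture("tf", fit_wa_tol(training_fixture()))
}

expect_close <- function(x, y, tol = 1e-9) {
  expect_true(all(abs(x - y) <= tol),
              label = sprintf("max |diff| = %g", max(abs(x - y))))
}
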