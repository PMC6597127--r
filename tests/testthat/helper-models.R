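# Shared fixtures, built once per test run.

# small symmetric tree with identical lobules (8 terminals)
toy_tree <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture("toy_symmetric_tree")
    cache
  }
})

# the default whole-lung geometry (304 lobules)
default_lung <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_lung()
    cache
  }
})

# short whole-lung washout with default geometry (shared across tests)
short_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_washout(simulation_config(
        protocol = breathing_protocol(n_breaths = 6)))
    cache
  }
})

# run n steps of the coupled model on a compiled mbw_model
run_steps <- function(model, protocol, nsteps, dt = model$numerics$dt) {
  for (s in seq_len(nsteps)) {
    Q <- protocol$Q_in(s * dt)
    step_ventilation(model, Q, dt)
    advance_concentration(model, Q, dt)
  }
  model_state(model)
}
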