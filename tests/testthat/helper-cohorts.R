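# Shared fixtures, built once per test run and memoized.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

ref_model <- function() memo("model", reference_model)

demo_cfg <- function() {
  memo("cfg", function() {
    pipeline_config(system.file("extdata", "demo_config.yaml",
                                package = "scarscreen"))
  })
}

# The packaged demo cohort (5,000 draws, fixed seed from the demo profile).
demo_cohort <- function() {
  memo("demo_cohort", function() {
    cfg <- demo_cfg()
    m <- ref_model()
    draws <- sample_parameters(m$default_params, cfg$n_simulations,
                               seed = cfg$master_seed)
    run_cohort(m, draws)
  })
}

demo_labels <- function() memo("demo_labels", function() {
  label_cohort(demo_cohort())
})

# Small cohort for structural unit tests where class mix, not precision,
# matters.
small_cohort <- function() {
  memo("small_cohort", function() {
    m <- ref_model()
    draws <- sample_parameters(m$default_params, 400, seed = 7)
    run_cohort(m, draws)
  })
}

# Single-state exponential-decay model: the closed-form limit used to
# validate the integrator.
decay_model <- function(k = 0.5) {
  kinetic_model(
    state_names = "X", param_names = "k",
    default_params = c(k = k), initial_state = c(X = 1),
    rhs = function(t, state, params) -params[["k"]] * state[["X"]],
    marker_roles = list(collagen = "X", fibroblast = "X",
                        screened = character(0)),
    name = "decay")
}

# Fixed-step RK4 oracle (independent integration route).
rk4_day40 <- function(model, params, dt = 1e-3, horizon = 40) {
  fn <- function(t, y, p) list(model$rhs(t, y, p))
  out <- deSolve::rk4(model$initial_state, times = seq(0, horizon, by = dt),
                      func = fn, parms = params)
  stats::setNames(as.numeric(out[nrow(out), -1]), model$state_names)
}

# Relative difference with an absolute floor for near-zero states.
rel_diff <- function(a, b, floor = 1e-8) {
  abs(a - b) / pmax(abs(a), abs(b), floor)
}
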