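test_that("integrator reproduces closed-form exponential decay", {
  m <- decay_model(0.5)
  tr <- simulate_trajectory(m, rtol = 1e-10, atol = 1e-18)
  expect_s3_class(tr, "trajectory")
  expect_identical(dim(tr), c(40L, 1L))
  expected <- exp(-0.5 * (1:40))
  expect_true(all(abs(tr[, "X"] - expected) / expected < 1e-4))
  expect_equal(tr[1, "X"], 0.60653, tolerance = 1e-4)
  expect_equal(tr[2, "X"], 0.36788, tolerance = 1e-4)
  expect_equal(tr[3, "X"], 0.22313, tolerance = 1e-4)
})

test_that("all-zero initial state yields the identically zero trajectory", {
  m <- ref_model()
  m0 <- kinetic_model(m$state_names, m$param_names, m$default_params,
                      stats::setNames(rep(0, 12), m$state_names),
                      m$rhs, m$marker_roles)
  tr <- simulate_trajectory(m0)
  expect_true(all(tr == 0))
})

test_that("decoupled surrogate states match their exponential solutions", {
  m <- ref_model()
  pars <- m$default_params
  production <- c("rI", "rI8", "rM", "rF", "gF", "pTP", "pTM", "pTF",
                  "p6", "p8P", "p8I", "p10", "p9", "pT1M", "pT1F", "pFN",
                  "pC")
  pars[production] <- 1e-12
  m1 <- kinetic_model(m$state_names, m$param_names, pars,
                      stats::setNames(rep(1, 12), m$state_names),
                      m$rhs, m$marker_roles)
  tr <- simulate_trajectory(m1, pars, rtol = 1e-10, atol = 1e-18)
  decay <- c(P = "kP", I = "dI", M = "dM", F = "aF", T = "dT", C6 = "d6",
             C8 = "d8", I10 = "d10", M9 = "d9", T1 = "dT1", FN = "dFN")
  for (s in names(decay)) {
    expected <- exp(-pars[[decay[[s]]]] * (1:40))
    ok <- expected > 1e-10   # below this, absolute tolerance dominates
    expect_true(all(abs(tr[ok, s] - expected[ok]) / expected[ok] < 1e-4),
                info = paste("state", s))
  }
})

test_that("adaptive solution matches the fixed-step RK4 oracle at day 40", {
  m <- ref_model()
  tr <- simulate_trajectory(m)
  oracle <- rk4_day40(m, m$default_params)
  expect_true(all(rel_diff(tr[40, ], oracle) < 1e-3))
})

test_that("injury signal decays strictly monotonically", {
  m <- ref_model()
  set.seed(11)
  for (i in 1:5) {
    pars <- m$default_params *
      exp(stats::runif(length(m$default_params), -0.5, 0.5))
    tr <- simulate_trajectory(m, pars)
    if (inherits(tr, "simulation_failure")) next
    expect_true(all(diff(tr[, "P"]) < 0))
  }
})

test_that("trajectories stay non-negative and finite under random draws", {
  m <- ref_model()
  draws <- sample_parameters(m$default_params, 60, seed = 3)
  for (i in seq_len(nrow(draws))) {
    tr <- simulate_trajectory(m, draws[i, ])
    if (inherits(tr, "simulation_failure")) next
    expect_true(all(is.finite(tr)))
    expect_true(all(tr >= 0))
  }
})

test_that("non-positive parameters produce a simulation failure, not output", {
  m <- decay_model()
  bad <- simulate_trajectory(m, c(k = -1))
  expect_s3_class(bad, "simulation_failure")
  expect_match(bad$message, "non-positive")
})

test_that("tidy export has one row per sim, day and state", {
  m <- ref_model()
  tr <- simulate_trajectory(m)
  td <- tidy_trajectories(tr)
  expect_identical(nrow(td), 40L * 12L)
  expect_named(td, c("sim_id", "day", "state", "value"))
  expect_equal(td$value[td$day == 40 & td$state == "COL"],
               unname(tr[40, "COL"]))
})
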