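test_that("kinetic_model validates its contract", {
  rhs <- function(t, state, params) rep(0, length(state))
  ok <- kinetic_model(c("A", "B"), "k", c(k = 1), c(A = 0, B = 1), rhs,
                      list(collagen = "A", fibroblast = "B",
                           screened = character(0)))
  expect_s3_class(ok, "kinetic_model")
  expect_error(
    kinetic_model(c("A", "B"), "k", c(k = 0), c(A = 0, B = 1), rhs,
                  list(collagen = "A", fibroblast = "B",
                       screened = character(0))),
    "strictly positive")
  expect_error(
    kinetic_model(c("A", "B"), "k", c(k = 1), c(A = -1, B = 1), rhs,
                  list(collagen = "A", fibroblast = "B",
                       screened = character(0))),
    "non-negative")
  expect_error(
    kinetic_model(c("A", "B"), "k", c(k = 1), c(A = 0, B = 1), rhs,
                  list(collagen = "A", fibroblast = "B", screened = "C")),
    "unknown states")
  expect_error(
    kinetic_model(c("A", "B"), "k", c(k = 1), c(A = 0, B = 1), rhs,
                  list(collagen = "A", fibroblast = "B", screened = "A")),
    "screened")
})

test_that("reference surrogate model loads with the expected structure", {
  m <- ref_model()
  expect_length(m$state_names, 12)
  expect_identical(m$marker_roles$collagen, "COL")
  expect_identical(m$marker_roles$fibroblast, "F")
  expect_setequal(m$marker_roles$screened,
                  c("T", "C6", "C8", "I10", "M9", "T1", "FN"))
  expect_true(all(m$default_params > 0))
  expect_true(all(m$initial_state >= 0))
  expect_identical(unname(m$initial_state["P"]), 1)
})

test_that("rhs evaluation matches hand computation on simple states", {
  m <- ref_model()
  pars <- m$default_params
  pars[c("kP", "rI", "pTP", "p8P")] <- c(0.5, 0.3, 0.2, 0.1)
  state <- stats::setNames(rep(0, 12), m$state_names)
  state["P"] <- 1
  d <- rhs_eval(m, 0, state, pars)
  expect_equal(unname(d["P"]), -0.5)
  expect_equal(unname(d["I"]), 0.3)
  expect_equal(unname(d["T"]), 0.2)
  expect_equal(unname(d["C8"]), 0.1)
  expect_equal(unname(d[setdiff(names(d), c("P", "I", "T", "C8"))]),
               rep(0, 8))
})

test_that("the all-zero state is a fixed point (no constitutive production)", {
  m <- ref_model()
  zero <- stats::setNames(rep(0, 12), m$state_names)
  expect_equal(unname(rhs_eval(m, 3, zero)), rep(0, 12))
})

test_that("logistic fibroblast growth vanishes at carrying capacity", {
  m <- ref_model()
  state <- stats::setNames(rep(0, 12), m$state_names)
  state["F"] <- m$default_params[["Fmax"]]
  d1 <- rhs_eval(m, 0, state)
  pars2 <- m$default_params
  pars2[["gF"]] <- pars2[["gF"]] * 17   # logistic term is zero at Fmax
  d2 <- rhs_eval(m, 0, state, pars2)
  expect_equal(unname(d1["F"]), unname(d2["F"]))
})

test_that("rhs_eval rejects contract violations", {
  m <- ref_model()
  expect_error(rhs_eval(m, 0, rep(0, 5)), "length")
  expect_error(rhs_eval(m, 0, rep(0, 12), rep(1, 3)), "length")
  bad <- stats::setNames(rep(0, 12), m$state_names)
  bad[1] <- NaN
  expect_error(rhs_eval(m, 0, bad), "non-finite")
})

test_that("pathological scenario halves aF and multiplies pC by 1.5", {
  pars <- c(aF = 0.4, pC = 1.0, other = 2.2)
  out <- pathological_scenario(pars)
  expect_equal(unname(out["aF"]), 0.2)
  expect_equal(unname(out["pC"]), 1.5)
  expect_identical(out["other"], pars["other"])
  twice <- pathological_scenario(out)
  expect_equal(unname(twice["aF"]), 0.1)
  expect_equal(unname(twice["pC"]), 2.25)
  expect_error(pathological_scenario(c(aF = 1)), "pC")
})
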