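#' Kinetic wound-healing model plug-in contract
#'
#' A `kinetic_model` bundles everything the cohort pipeline needs to know
#' about a wound-healing rate-equation model: the ordered state and parameter
#' names, strictly positive default parameter values, a non-negative initial
#' state, the right-hand-side (derivative) function, and a role map that
#' designates which state is the collagen readout, which is the fibroblast
#' readout, and which protein states are screened as biomarker candidates.
#'
#' The derivative function has signature `rhs(t, state, params)` with time in
#' days and must return a finite numeric vector of the same length as
#' `state`. The contract is for ordinary (delay-free) systems; a model with
#' explicit delays would need an extended signature carrying lagged states,
#' which this contract deliberately does not define.
#'
#' @param state_names Character vector of state identifiers (unique).
#' @param param_names Character vector of parameter identifiers (unique).
#' @param default_params Named numeric vector of strictly positive defaults,
#'   one per parameter (per-day rates, dimensionless saturation constants,
#'   arbitrary concentration units).
#' @param initial_state Named numeric vector of non-negative initial values,
#'   one per state.
#' @param rhs Function `(t, state, params) -> derivative vector`.
#' @param marker_roles List with elements `collagen` (one state name),
#'   `fibroblast` (one state name) and `screened` (character vector of
#'   protein states, excluding the collagen state).
#' @param name Short model identifier used in output provenance.
#'
#' @return An object of class `kinetic_model`.
#' @export
kinetic_model <- function(state_names, param_names, default_params,
                          initial_state, rhs, marker_roles,
                          name = "user_model") {
  stopifnot(is.character(state_names), length(state_names) >= 1,
            !anyDuplicated(state_names),
            is.character(param_names), length(param_names) >= 1,
            !anyDuplicated(param_names),
            is.function(rhs))
  default_params <- default_params[param_names]
  initial_state <- initial_state[state_names]
  if (anyNA(default_params) || !all(is.finite(default_params)) ||
      any(default_params <= 0)) {
    stop("every default parameter must be a strictly positive finite value")
  }
  if (anyNA(initial_state) || !all(is.finite(initial_state)) ||
      any(initial_state < 0)) {
    stop("every initial state must be a non-negative finite value")
  }
  roles <- marker_roles
  if (!is.list(roles) ||
      !all(c("collagen", "fibroblast", "screened") %in% names(roles))) {
    stop("marker_roles must list 'collagen', 'fibroblast' and 'screened'")
  }
  if (length(roles$collagen) != 1L || length(roles$fibroblast) != 1L) {
    stop("exactly one state must carry the 'collagen' role and one the ",
         "'fibroblast' role")
  }
  all_roles <- c(roles$collagen, roles$fibroblast, roles$screened)
  missing <- setdiff(all_roles, state_names)
  if (length(missing)) {
    stop("marker_roles reference unknown states: ",
         paste(missing, collapse = ", "))
  }
  if (roles$collagen %in% roles$screened) {
    stop("the collagen state must not be in the screened set")
  }
  structure(
    list(state_names = state_names, param_names = param_names,
         default_params = default_params, initial_state = initial_state,
         rhs = rhs, marker_roles = roles, name = name),
    class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("<kinetic_model> ", x$name, "\n", sep = "")
  cat("  states (", length(x$state_names), "): ",
      paste(x$state_names, collapse = ", "), "\n", sep = "")
  cat("  parameters: ", length(x$param_names), "\n", sep = "")
  cat("  roles: collagen=", x$marker_roles$collagen,
      ", fibroblast=", x$marker_roles$fibroblast,
      ", screened={", paste(x$marker_roles$screened, collapse = ", "),
      "}\n", sep = "")
  invisible(x)
}

#' Evaluate a model's derivative function with contract checks
#'
#' @param model A [kinetic_model()].
#' @param t Time in days.
#' @param state Numeric state vector, same length/order as
#'   `model$state_names`.
#' @param params Numeric parameter vector, same length/order as
#'   `model$param_names` (defaults to the model defaults).
#'
#' @return The derivative vector, named by state.
#' @export
rhs_eval <- function(model, t, state, params = model$default_params) {
  stopifnot(inherits(model, "kinetic_model"))
  if (length(state) != length(model$state_names)) {
    stop("state has length ", length(state), ", expected ",
         length(model$state_names))
  }
  if (length(params) != length(model$param_names)) {
    stop("params has length ", length(params), ", expected ",
         length(model$param_names))
  }
  if (!all(is.finite(state)) || !all(is.finite(params))) {
    stop("non-finite state or parameter values rejected")
  }
  state <- stats::setNames(as.numeric(state), model$state_names)
  params <- stats::setNames(as.numeric(params), model$param_names)
  d <- model$rhs(t, state, params)
  if (length(d) != length(state)) {
    stop("rhs returned ", length(d), " derivatives for ",
         length(state), " states")
  }
  stats::setNames(as.numeric(d), model$state_names)
}

# Derivatives of the 12-state reference wound-healing system. `state` and
# `params` arrive as named vectors; positional access keeps this hot path
# cheap (it is called ~1e3 times per simulated wound).
surrogate_rhs <- function(t, state, params) {
  P <- state[[1L]]; I <- state[[2L]]; M <- state[[3L]]; F <- state[[4L]]
  Tb <- state[[5L]]; C6 <- state[[6L]]; C8 <- state[[7L]]
  I10 <- state[[8L]]; M9 <- state[[9L]]; T1 <- state[[10L]]
  FN <- state[[11L]]; COL <- state[[12L]]
  p <- params
  inh10 <- 1 / (1 + I10 / p[["KI10"]])   # IL-10 inhibition of inflammation
  actT <- Tb / (p[["KT"]] + Tb)          # TGF-beta saturation
  c(
    -p[["kP"]] * P,
    p[["rI"]] * P + p[["rI8"]] * C8 / (p[["K8"]] + C8) * inh10 -
      p[["dI"]] * I,
    p[["rM"]] * I - p[["dM"]] * M,
    p[["rF"]] * actT + p[["gF"]] * F * (1 - F / p[["Fmax"]]) -
      p[["aF"]] * F,
    p[["pTP"]] * P + p[["pTM"]] * M + p[["pTF"]] * F - p[["dT"]] * Tb,
    p[["p6"]] * I * inh10 - p[["d6"]] * C6,
    p[["p8P"]] * P + p[["p8I"]] * I - p[["d8"]] * C8,
    p[["p10"]] * M - p[["d10"]] * I10,
    p[["p9"]] * I - p[["d9"]] * M9,
    p[["pT1M"]] * M +
      p[["pT1F"]] * F * (1 + p[["e10"]] * I10 / (p[["K10e"]] + I10)) -
      p[["dT1"]] * T1,
    p[["pFN"]] * F * actT - p[["dFN"]] * FN,
    p[["pC"]] * F * actT - p[["dC"]] * COL * M9 / (1 + T1 / p[["KT1"]])
  )
}

#' Reference surrogate wound-healing model
#'
#' A calibrated twelve-state kinetic model of injury-initiated wound
#' healing: platelets (P) decay after wounding and recruit inflammatory
#' cells (I), which give rise to repair macrophages (M); TGF-beta (T) is
#' released by platelets, macrophages and fibroblasts (F) and drives
#' fibroblast recruitment, fibronectin (FN) deposition and collagen (COL)
#' production; the inflammatory cytokines IL-6 (C6) and CXCL8 (C8) amplify
#' inflammation while IL-10 (I10), produced by macrophages, resolves it and
#' enhances TIMP-1 (T1) production; MMP-9 (M9) degrades collagen and is
#' inhibited by TIMP-1. Fibroblast growth is logistic with carrying capacity
#' `Fmax`, opposed by the apoptosis rate `aF`. Concentrations are in
#' arbitrary units; all rates are per day.
#'
#' The shipped default parameters are calibrated so that (i) the
#' default-parameter run resolves inflammation and plateaus collagen by day
#' 40 (normal healing), (ii) halving fibroblast apoptosis while raising
#' collagen production 1.5-fold ([pathological_scenario()]) produces at
#' least fivefold day-40 collagen and fibroblast fold changes, and (iii)
#' random 0.5-2x parameter perturbation yields a mix of normal, mild and
#' severe scarring outcomes (see [check_calibration()]).
#'
#' @param config_file YAML file with the model names, defaults, initial
#'   state and role map. Defaults to the packaged calibrated configuration.
#'
#' @return A [kinetic_model()] with 12 states and 30 parameters; screened
#'   proteins are TGF-beta, IL-6, CXCL8, IL-10, MMP-9, TIMP-1 and
#'   fibronectin.
#' @export
reference_model <- function(config_file = system.file(
                              "extdata", "surrogate_model.yaml",
                              package = "scarscreen", mustWork = TRUE)) {
  cfg <- yaml::read_yaml(config_file)
  kinetic_model(
    state_names = cfg$state_names,
    param_names = names(cfg$default_params),
    default_params = unlist(cfg$default_params),
    initial_state = unlist(cfg$initial_state)[cfg$state_names],
    rhs = surrogate_rhs,
    marker_roles = cfg$marker_roles,
    name = cfg$name %||% "wound_surrogate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-parameter pathological-scarring scenario
#'
#' Returns a copy of `params` with the fibroblast apoptosis rate `aF`
#' halved and the collagen production rate `pC` multiplied by 1.5, the
#' perturbation used to represent a prototypical pathological-scarring
#' wound. The operation composes (applying it twice gives `aF/4` and
#' `2.25 * pC`); all other parameters are returned unchanged.
#'
#' @param params Named parameter vector containing `aF` and `pC`.
#' @return The perturbed parameter vector.
#' @export
pathological_scenario <- function(params) {
  if (!all(c("aF", "pC") %in% names(params))) {
    stop("params must contain the fibroblast apoptosis rate 'aF' and the ",
         "collagen production rate 'pC'")
  }
  params[["aF"]] <- params[["aF"]] / 2
  params[["pC"]] <- params[["pC"]] * 1.5
  params
}
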