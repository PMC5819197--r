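#' Simulate daily wound-healing trajectories
#'
#' Integrates a [kinetic_model()] from its initial state with an adaptive
#' solver (deSolve `lsoda`, relative tolerance 1e-6) and returns the state
#' values on the daily grid t = 1, ..., `horizon` days post-wounding. The
#' t = 0 initial state is not part of the returned trajectory. Values in
#' (-1e-9, 0) arising from integrator round-off are clamped to 0; more
#' negative values, non-finite values, or solver failure produce a
#' simulation-failure result rather than a partial trajectory.
#'
#' @param model A [kinetic_model()].
#' @param params Parameter vector (defaults to the model defaults).
#' @param horizon Final day, >= 1 (default 40).
#' @param rtol,atol Integrator tolerances.
#'
#' @return On success, a `horizon` x n_states numeric matrix of class
#'   `trajectory` (rows named by day, columns by state, attribute `days`).
#'   On failure, an object of class `simulation_failure` carrying a
#'   `message`.
#' @export
simulate_trajectory <- function(model, params = model$default_params,
                                horizon = 40, rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(model, "kinetic_model"), horizon >= 1)
  if (length(params) != length(model$param_names)) {
    stop("params has length ", length(params), ", expected ",
         length(model$param_names))
  }
  if (any(!is.finite(params)) || any(params <= 0)) {
    return(simulation_failure("non-positive or non-finite parameter value"))
  }
  params <- stats::setNames(as.numeric(params), model$param_names)
  y0 <- model$initial_state
  rhs <- model$rhs
  fn <- function(t, y, p) list(rhs(t, y, p))
  times <- c(0, seq_len(horizon))
  out <- tryCatch(
    suppressWarnings(
      deSolve::lsoda(y = y0, times = times, func = fn, parms = params,
                     rtol = rtol, atol = atol)),
    error = function(e) e)
  if (inherits(out, "error")) {
    return(simulation_failure(conditionMessage(out)))
  }
  istate <- attr(out, "istate")
  if ((!is.null(istate) && istate[1] < 0) ||
      nrow(out) != length(times) || !all(is.finite(out))) {
    return(simulation_failure("integrator did not reach the horizon"))
  }
  traj <- out[-1, -1, drop = FALSE]
  if (any(traj < -1e-9)) {
    return(simulation_failure(sprintf(
      "negative state value %.3g beyond clamping tolerance", min(traj))))
  }
  traj[traj < 0] <- 0
  dimnames(traj) <- list(seq_len(horizon), model$state_names)
  structure(traj, days = seq_len(horizon), class = c("trajectory", "matrix"))
}

simulation_failure <- function(message) {
  structure(list(message = message), class = "simulation_failure")
}

#' @export
print.simulation_failure <- function(x, ...) {
  cat("<simulation_failure>", x$message, "\n")
  invisible(x)
}

#' Convert a trajectory (or list of trajectories) to tidy long format
#'
#' @param trajectories A single `trajectory` matrix or a named list of them.
#' @return A data.frame with columns `sim_id`, `day`, `state`, `value`.
#' @export
tidy_trajectories <- function(trajectories) {
  if (inherits(trajectories, "trajectory")) {
    trajectories <- list(reference = trajectories)
  }
  out <- lapply(names(trajectories), function(id) {
    tr <- trajectories[[id]]
    data.frame(sim_id = id,
               day = rep(as.integer(rownames(tr)), times = ncol(tr)),
               state = rep(colnames(tr), each = nrow(tr)),
               value = as.vector(tr),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
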