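#' Sample a perturbed parameter ensemble
#'
#' Draws `n` parameter vectors with every parameter sampled independently
#' from the interval between one-half and double its default value,
#' emulating natural inter-individual variability in the rates of the
#' wound-healing processes. Sampling is uniform on the interval by default;
#' `log_uniform = TRUE` samples uniformly on the log scale instead (same
#' bounds). Identical `(defaults, n, seed)` give bitwise-identical draws.
#'
#' @param defaults Named vector of strictly positive default parameters.
#' @param n Number of draws, >= 1.
#' @param seed Integer seed for the sampler.
#' @param log_uniform Sample log-uniformly instead of uniformly.
#'
#' @return An `n` x p numeric matrix (rows `draw_id` 1..n, columns named by
#'   parameter) with attribute `bounds`, the 2 x p matrix of per-parameter
#'   sampling intervals.
#' @export
sample_parameters <- function(defaults, n, seed, log_uniform = FALSE) {
  stopifnot(n >= 1, length(defaults) >= 1)
  if (any(!is.finite(defaults)) || any(defaults <= 0)) {
    stop("sampling intervals [theta/2, 2*theta] require strictly positive ",
         "default parameters")
  }
  lo <- defaults / 2
  hi <- defaults * 2
  p <- length(defaults)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  u <- matrix(stats::runif(n * p), nrow = n, ncol = p)
  values <- if (log_uniform) {
    exp(sweep(sweep(u, 2, log(hi) - log(lo), `*`), 2, log(lo), `+`))
  } else {
    sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  }
  dimnames(values) <- list(seq_len(n), names(defaults))
  attr(values, "bounds") <- rbind(lo = lo, hi = hi)
  values
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Run a virtual cohort of wound-healing simulations
#'
#' Simulates one trajectory per parameter draw plus the unperturbed
#' reference (default-parameter) trajectory. Integration is deterministic,
#' so the result depends only on the draws; failed integrations are
#' recorded with their draw id and reason, never silently dropped, and a
#' warning is raised if more than 1% of draws fail.
#'
#' @param model A [kinetic_model()].
#' @param draws Matrix of parameter draws from [sample_parameters()].
#' @param horizon Final day (default 40).
#' @param progress_every Report progress every this many draws (0 = quiet).
#'
#' @return An object of class `cohort` with elements `model_name`,
#'   `reference` (the default-parameter `trajectory`), `draws`,
#'   `trajectories` (an n_ok x days x states array with draw ids as row
#'   names), `failures` (data.frame `draw_id`, `reason`) and `horizon`.
#' @export
run_cohort <- function(model, draws, horizon = 40, progress_every = 0) {
  stopifnot(inherits(model, "kinetic_model"), nrow(draws) >= 1)
  if (!identical(colnames(draws), model$param_names)) {
    draws <- draws[, model$param_names, drop = FALSE]
  }
  reference <- simulate_trajectory(model, horizon = horizon)
  if (inherits(reference, "simulation_failure")) {
    stop("reference simulation failed: ", reference$message)
  }
  n <- nrow(draws)
  n_states <- length(model$state_names)
  traj <- array(NA_real_, dim = c(n, horizon, n_states),
                dimnames = list(seq_len(n), seq_len(horizon),
                                model$state_names))
  fail_id <- integer(0)
  fail_reason <- character(0)
  for (i in seq_len(n)) {
    res <- simulate_trajectory(model, draws[i, ], horizon = horizon)
    if (inherits(res, "simulation_failure")) {
      fail_id <- c(fail_id, i)
      fail_reason <- c(fail_reason, res$message)
    } else {
      traj[i, , ] <- res
    }
    if (progress_every > 0 && i %% progress_every == 0) {
      message("simulated ", i, "/", n, " draws")
    }
  }
  if (length(fail_id)) {
    traj <- traj[-fail_id, , , drop = FALSE]
  }
  if (length(fail_id) > 0.01 * n) {
    warning(sprintf("%d of %d cohort simulations failed (> 1%%)",
                    length(fail_id), n))
  }
  structure(
    list(model_name = model$name,
         marker_roles = model$marker_roles,
         reference = reference,
         draws = draws,
         trajectories = traj,
         failures = data.frame(draw_id = fail_id, reason = fail_reason,
                               stringsAsFactors = FALSE),
         horizon = horizon),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> model=", x$model_name, ": ", nrow(x$draws), " draws, ",
      nrow(x$failures), " failures, horizon ", x$horizon, " days\n",
      sep = "")
  invisible(x)
}

#' Extract per-draw concentrations of one state on one day
#'
#' @param cohort A `cohort`.
#' @param state State name.
#' @param day Day on the daily grid.
#' @return Named numeric vector (names are draw ids of successful draws).
#' @export
cohort_values <- function(cohort, state, day) {
  stopifnot(inherits(cohort, "cohort"),
            state %in% dimnames(cohort$trajectories)[[3]],
            day >= 1, day <= cohort$horizon)
  cohort$trajectories[, day, state]
}
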