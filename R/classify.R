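#' Day-40 fold changes of collagen and fibroblasts versus normal healing
#'
#' For every successful draw, divides the day-`horizon` collagen and
#' fibroblast concentrations by the corresponding values of the reference
#' (default-parameter, normal-healing) simulation.
#'
#' @param cohort A `cohort` from [run_cohort()].
#' @return data.frame with columns `draw_id`, `fc_col`, `fc_fib`.
#' @export
fold_changes <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  roles <- cohort$marker_roles
  day <- cohort$horizon
  ref_col <- cohort$reference[day, roles$collagen]
  ref_fib <- cohort$reference[day, roles$fibroblast]
  if (ref_col <= 0) {
    stop("reference day-", day, " value of collagen state '",
         roles$collagen, "' is not positive; fold changes undefined")
  }
  if (ref_fib <= 0) {
    stop("reference day-", day, " value of fibroblast state '",
         roles$fibroblast, "' is not positive; fold changes undefined")
  }
  data.frame(
    draw_id = as.integer(rownames(cohort$trajectories)),
    fc_col = cohort$trajectories[, day, roles$collagen] / ref_col,
    fc_fib = cohort$trajectories[, day, roles$fibroblast] / ref_fib,
    row.names = NULL)
}

#' Four-way scarring outcome from collagen and fibroblast fold changes
#'
#' Applies the literal threshold rules jointly to both fold changes:
#' "normal" when neither exceeds `normal_max`; "mild" when both lie in
#' `[mild_lo, mild_hi]`; "severe" when both strictly exceed `mild_hi`; any
#' other combination (including mixed pairs such as one fold change below 5
#' and the other above 10) is "excluded" as not clearly classifiable.
#'
#' @param fc_col,fc_fib Numeric vectors of fold changes (recycled
#'   together).
#' @param thresholds List with `normal_max` (default 1), `mild_lo` (5) and
#'   `mild_hi` (10).
#' @return Factor with levels normal, mild, severe, excluded.
#' @export
classify_outcome <- function(fc_col, fc_fib,
                             thresholds = list(normal_max = 1,
                                               mild_lo = 5, mild_hi = 10)) {
  stopifnot(length(fc_col) == length(fc_fib))
  if (any(!is.finite(fc_col) | !is.finite(fc_fib)) ||
      any(fc_col < 0 | fc_fib < 0)) {
    stop("fold changes must be finite and non-negative")
  }
  th <- thresholds
  out <- rep("excluded", length(fc_col))
  out[fc_col <= th$normal_max & fc_fib <= th$normal_max] <- "normal"
  out[fc_col >= th$mild_lo & fc_col <= th$mild_hi &
        fc_fib >= th$mild_lo & fc_fib <= th$mild_hi] <- "mild"
  out[fc_col > th$mild_hi & fc_fib > th$mild_hi] <- "severe"
  factor(out, levels = c("normal", "mild", "severe", "excluded"))
}

#' Binary scarring outcome from the collagen fold change alone
#'
#' Labels a simulation "pathological" when its day-40 collagen fold change
#' strictly exceeds `cutoff`, and "normal" otherwise. The fibroblast fold
#' change plays no role here: the binary label is defined for every
#' successful draw (including draws the four-way rule excludes) and is the
#' outcome used by the logistic-regression evaluation.
#'
#' @param fc_col Numeric vector of collagen fold changes.
#' @param cutoff Threshold (default 10, strict inequality).
#' @return Factor with levels normal, pathological.
#' @export
binary_outcome <- function(fc_col, cutoff = 10) {
  if (any(!is.finite(fc_col))) stop("fold changes must be finite")
  factor(ifelse(fc_col > cutoff, "pathological", "normal"),
         levels = c("normal", "pathological"))
}

#' Label every draw of a cohort
#'
#' Convenience wrapper: computes fold changes, the four-way class and the
#' binary class for all successful draws.
#'
#' @inheritParams fold_changes
#' @inheritParams classify_outcome
#' @return data.frame `draw_id`, `fc_col`, `fc_fib`, `class4`, `binary`.
#' @export
label_cohort <- function(cohort,
                         thresholds = list(normal_max = 1,
                                           mild_lo = 5, mild_hi = 10)) {
  fc <- fold_changes(cohort)
  fc$class4 <- classify_outcome(fc$fc_col, fc$fc_fib, thresholds)
  fc$binary <- binary_outcome(fc$fc_col, thresholds$mild_hi)
  fc
}
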