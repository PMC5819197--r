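#' Plot concentration distribution curves for one protein and day
#'
#' Percentage-of-simulations curves (one per outcome group, each binned
#' over its own range) for a screened protein on a given day.
#'
#' @inheritParams distribution_curves
#' @return A ggplot object.
#' @export
plot_distribution_curves <- function(cohort, labels, protein, day,
                                     n_bins = 50) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
  df <- distribution_curves(cohort, labels, protein, day, n_bins)
  ggplot2::ggplot(df, ggplot2::aes(x = conc, y = percent, colour = group)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(normal = "#1b9e77", mild = "#e78ac3", severe = "#e7298a")) +
    ggplot2::labs(x = paste0("[", protein, "] (a.u.)"),
                  y = "% of simulations",
                  title = paste0(protein, ", day ", day)) +
    ggplot2::theme_minimal()
}

#' Plot ROC curves for all panels of one evaluation day
#'
#' @param evaluation A `panel_evaluation` from [evaluate_panels()].
#' @param day Which evaluated day to plot.
#' @return A ggplot object.
#' @export
plot_roc_curves <- function(evaluation, day) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
  key <- paste0("day", day)
  stopifnot(key %in% names(evaluation))
  dayres <- evaluation[[key]]
  df <- do.call(rbind, lapply(names(dayres$panels), function(pn) {
    p <- dayres$panels[[pn]]
    data.frame(panel = sprintf("%s (AUC %.2f)", pn, p$auc),
               fpr = p$roc$fpr, tpr = p$roc$tpr)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = fpr, y = tpr, colour = panel)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = paste("ROC curves, day", day)) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("conc", "percent", "group", "fpr", "tpr",
                         "panel"))
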