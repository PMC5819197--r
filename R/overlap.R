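#' Fractional concentration histogram
#'
#' Bins concentration values into `n_bins` equal-width bins over `range`
#' and returns the fraction of values per bin (counts divided by the total
#' number of values), the representation used for the concentration
#' distribution curves. Bins are right-open except the last, which is
#' closed, so every in-range value falls in exactly one bin. A degenerate
#' range (lo == hi, e.g. a single-valued group) is widened symmetrically by
#' a relative epsilon so that the distribution remains representable.
#'
#' @param values Numeric vector of concentrations (>= 1 value).
#' @param n_bins Number of bins (default 50).
#' @param range Length-2 enclosing range; defaults to range(values).
#'
#' @return List of class `conc_histogram`: `bin_edges` (n_bins + 1
#'   increasing reals), `fractions` (n_bins non-negative reals summing to
#'   1), `n` (number of values).
#' @export
conc_histogram <- function(values, n_bins = 50, range = NULL) {
  stopifnot(length(values) >= 1, all(is.finite(values)), n_bins >= 1)
  if (is.null(range)) range <- base::range(values)
  lo <- range[1]; hi <- range[2]
  if (lo > hi) stop("invalid range: lo > hi")
  if (lo == hi) {
    eps <- max(1e-12, 1e-9 * abs(lo))
    lo <- lo - eps
    hi <- hi + eps
  }
  if (any(values < lo | values > hi)) {
    stop("values outside the histogram range; pass an enclosing range")
  }
  edges <- seq(lo, hi, length.out = n_bins + 1)
  idx <- findInterval(values, edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges, fractions = counts / length(values),
                 n = length(values)),
            class = "conc_histogram")
}

#' Bhattacharyya coefficient between two binned distributions
#'
#' BC = sum_i sqrt(p_i * q_i) over shared bins: 1 for identical
#' distributions, 0 for disjoint support. The two histograms must be built
#' on identical bin edges; comparing histograms binned over different
#' ranges is a contract violation because the coefficient is only defined
#' on a common partition of the concentration axis.
#'
#' @param h1,h2 `conc_histogram` objects with identical `bin_edges`.
#' @return The coefficient, a number in \[0, 1\].
#' @export
bhattacharyya <- function(h1, h2) {
  stopifnot(inherits(h1, "conc_histogram"), inherits(h2, "conc_histogram"))
  if (length(h1$bin_edges) != length(h2$bin_edges) ||
      any(abs(h1$bin_edges - h2$bin_edges) >
            1e-9 * (1 + abs(h1$bin_edges)))) {
    stop("histograms must share identical bin edges")
  }
  bc <- sum(sqrt(h1$fractions * h2$fractions))
  min(max(bc, 0), 1)
}

#' Relative overlap reduction between two days
#'
#' Expresses how much smaller the distribution overlap is at a later day
#' than at an earlier one: `100 * (bc_early - bc_late) / bc_early` percent.
#' Positive values mean less overlap (better separation) later; a negative
#' value (overlap grew) is passed through unmodified.
#'
#' @param bc_early,bc_late Bhattacharyya coefficients at the earlier and
#'   later day; `bc_early` must be > 0 (zero early overlap leaves the
#'   reduction undefined and returns NA).
#' @return Percent reduction (or NA when undefined).
#' @export
overlap_reduction <- function(bc_early, bc_late) {
  ifelse(bc_early > 0, 100 * (bc_early - bc_late) / bc_early, NA_real_)
}

#' Screen proteins by concentration-distribution overlap
#'
#' For each screened protein and requested day, bins the protein's
#' concentrations in the normal-healing group and in each pathological
#' group (mild, severe) over the pooled range of the two groups under
#' comparison (shared 50-bin partition) and computes the Bhattacharyya
#' coefficient of the two distributions. Draws with class4 = "excluded"
#' never enter the histograms. Proteins are ranked per day by the mean of
#' the normal-vs-mild and normal-vs-severe coefficients, ascending, so the
#' protein with the least overlap — the one most consistently elevated or
#' decreased in pathological scarring — ranks first. Day-40 rankings are
#' reported as diagnostic, earlier days as prognostic.
#'
#' @param cohort A `cohort`.
#' @param labels Labels from [label_cohort()].
#' @param days Days to screen (default c(7, 14, 21, 40)).
#' @param proteins Protein states to screen; defaults to the model's
#'   screened set. Requesting a state outside the screened set is an error.
#' @param n_bins Number of histogram bins (default 50).
#'
#' @return List of class `overlap_screen`: `overlaps` (data.frame
#'   `protein`, `day`, `pair`, `bc`, `n_normal`, `n_path`) and `ranking`
#'   (data.frame `day`, `role`, `rank`, `protein`, `mean_bc`,
#'   `bc_normal_vs_mild`, `bc_normal_vs_severe`).
#' @export
screen_overlap <- function(cohort, labels, days = c(7, 14, 21, 40),
                           proteins = NULL, n_bins = 50) {
  stopifnot(inherits(cohort, "cohort"))
  screened <- cohort$marker_roles$screened
  if (is.null(proteins)) proteins <- screened
  bad <- setdiff(proteins, screened)
  if (length(bad)) {
    stop("not in the screened protein set: ", paste(bad, collapse = ", "))
  }
  ids <- as.integer(rownames(cohort$trajectories))
  class4 <- labels$class4[match(ids, labels$draw_id)]
  groups <- list(normal = which(class4 == "normal"),
                 mild = which(class4 == "mild"),
                 severe = which(class4 == "severe"))
  rows <- list()
  for (day in days) {
    for (prot in proteins) {
      vals <- cohort$trajectories[, day, prot]
      for (path_grp in c("mild", "severe")) {
        if (!length(groups$normal) || !length(groups[[path_grp]])) {
          warning("empty group for pair normal-vs-", path_grp,
                  "; pair skipped")
          next
        }
        v1 <- vals[groups$normal]
        v2 <- vals[groups[[path_grp]]]
        shared <- base::range(c(v1, v2))
        h1 <- conc_histogram(v1, n_bins, shared)
        h2 <- conc_histogram(v2, n_bins, shared)
        rows[[length(rows) + 1L]] <- data.frame(
          protein = prot, day = day,
          pair = paste0("normal_vs_", path_grp),
          bc = bhattacharyya(h1, h2),
          n_normal = length(v1), n_path = length(v2),
          stringsAsFactors = FALSE)
      }
    }
  }
  overlaps <- do.call(rbind, rows)
  ranking <- do.call(rbind, lapply(days, function(day) {
    sub <- overlaps[overlaps$day == day, ]
    if (!nrow(sub)) return(NULL)
    wide <- stats::reshape(sub[, c("protein", "pair", "bc")],
                           idvar = "protein", timevar = "pair",
                           direction = "wide")
    names(wide) <- sub("^bc\\.", "bc_", names(wide))
    bc_cols <- grep("^bc_", names(wide), value = TRUE)
    wide$mean_bc <- rowMeans(wide[, bc_cols, drop = FALSE])
    wide <- wide[order(wide$mean_bc), ]
    wide$rank <- seq_len(nrow(wide))
    wide$day <- day
    wide$role <- if (day == cohort$horizon) "diagnostic" else "prognostic"
    wide[, c("day", "role", "rank", "protein", "mean_bc", bc_cols)]
  }))
  rownames(ranking) <- NULL
  structure(list(overlaps = overlaps, ranking = ranking, n_bins = n_bins),
            class = "overlap_screen")
}

#' @export
print.overlap_screen <- function(x, ...) {
  cat("<overlap_screen> ", nrow(x$overlaps), " protein-day-pair overlaps, ",
      x$n_bins, " bins\n", sep = "")
  print(utils::head(x$ranking, 12))
  invisible(x)
}

#' Per-group distribution curves for plotting
#'
#' Bins one protein's concentrations separately per outcome group, each
#' over its own min-max range (the plotting convention for the
#' concentration distribution curves; overlap quantification uses shared
#' bins instead, see [screen_overlap()]).
#'
#' @inheritParams screen_overlap
#' @param protein One screened protein.
#' @param day One day.
#' @return data.frame `group`, `conc` (bin midpoint), `percent`.
#' @export
distribution_curves <- function(cohort, labels, protein, day, n_bins = 50) {
  ids <- as.integer(rownames(cohort$trajectories))
  class4 <- labels$class4[match(ids, labels$draw_id)]
  vals <- cohort$trajectories[, day, protein]
  out <- lapply(c("normal", "mild", "severe"), function(g) {
    v <- vals[which(class4 == g)]
    if (!length(v)) return(NULL)
    h <- conc_histogram(v, n_bins)
    mids <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
    data.frame(group = g, conc = mids, percent = 100 * h$fractions,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
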