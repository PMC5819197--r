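#' @keywords internal
#' Coerce outcome labels to 0/1 with 1 = pathological (positive class).
as_binary01 <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must have exactly two levels")
    y <- as.integer(labels) - 1L
  } else if (is.logical(labels)) {
    y <- as.integer(labels)
  } else if (all(labels %in% c(0, 1))) {
    y <- as.integer(labels)
  } else {
    stop("labels must be a two-level factor, logical, or 0/1 vector")
  }
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present")
  }
  y
}

# DeLong placement values. For positives X (m) and negatives Y (n) the
# placement of a positive is the fraction of negatives it beats (ties count
# one half); AUC is the mean placement. Midranks give O((m+n) log(m+n)).
delong_placements <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n              # per-positive
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m      # per-negative
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' Area under the ROC curve (Mann-Whitney with midranks)
#'
#' AUC equals the probability that a randomly chosen pathological case
#' scores above a randomly chosen normal case, with ties counting one
#' half, and coincides with the trapezoidal area under the empirical ROC
#' curve.
#'
#' @param scores Numeric risk scores (higher = more pathological).
#' @param labels Outcome labels; the second factor level (or 1) is the
#'   positive, pathological class.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  delong_placements(scores, as_binary01(labels))$auc
}

#' Empirical ROC curve points
#'
#' @inheritParams roc_auc
#' @return data.frame `threshold`, `fpr`, `tpr`, starting at (0,0) and
#'   ending at (1,1) with both coordinates non-decreasing.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary01(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  # one point per distinct threshold (call positive when score >= threshold)
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(yy)[keep]
  fp <- cumsum(1 - yy)[keep]
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fp / sum(1 - y)),
             tpr = c(0, tp / sum(y)))
}

#' AUC confidence interval with the DeLong variance
#'
#' Wald interval `auc +/- z * sqrt(var)` on the AUC scale, clipped to
#' \[0, 1\], where `var = S10/m + S01/n` from the DeLong placement-value
#' variances. A degenerate variance (e.g. perfect separation, where every
#' placement equals 1) yields the collapsed interval `[auc, auc]` with
#' `degenerate = TRUE`.
#'
#' @inheritParams roc_auc
#' @param level Confidence level (default 0.95).
#' @return List `auc`, `var`, `ci` (length-2), `degenerate`.
#' @export
auc_ci <- function(scores, labels, level = 0.95) {
  y <- as_binary01(labels)
  if (sum(y) < 2 || sum(1 - y) < 2) {
    stop("need at least 2 observations per class")
  }
  pl <- delong_placements(scores, y)
  v <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  degenerate <- !is.finite(v) || v <= 0
  if (degenerate) {
    ci <- c(pl$auc, pl$auc)
  } else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- pmin(pmax(pl$auc + c(-1, 1) * z * sqrt(v), 0), 1)
  }
  list(auc = pl$auc, var = if (degenerate) 0 else v, ci = ci,
       degenerate = degenerate)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two risk scores computed on the same cases (paired
#' design) using the covariance of their DeLong placement values:
#' `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov)`, with a two-sided
#' normal p-value. Swapping the scores negates `z` and leaves `p`
#' unchanged. A zero variance of the difference with equal AUCs (e.g.
#' identical scores) returns `p = 1` with `degenerate = TRUE`.
#'
#' @param scores_a,scores_b Risk scores for the same observations.
#' @inheritParams roc_auc
#' @return List `auc_a`, `auc_b`, `diff`, `z`, `p`, `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  y <- as_binary01(labels)
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  d10 <- pa$v10 - pb$v10
  d01 <- pa$v01 - pb$v01
  v <- stats::var(d10) / pa$m + stats::var(d01) / pa$n
  diff <- pa$auc - pb$auc
  if (!is.finite(v) || v <= 0) {
    z <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
    return(list(auc_a = pa$auc, auc_b = pb$auc, diff = diff, z = z, p = p,
                degenerate = TRUE))
  }
  z <- diff / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, diff = diff, z = z,
       p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}
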