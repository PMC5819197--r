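#' Min-max normalize marker concentrations
#'
#' Scales each column to \[0, 1\] over the cohort. The scaling is an
#' affine reparameterization that the logistic model absorbs into its
#' coefficients and intercept, so fitted probabilities and AUCs are
#' unchanged by it; it is applied so that regression coefficients are
#' comparable across markers.
#'
#' @param x Numeric vector or matrix/data.frame of marker concentrations.
#' @return The rescaled object.
#' @export
normalize_minmax <- function(x) {
  scale1 <- function(v, nm) {
    r <- range(v)
    if (!all(is.finite(r))) stop("non-finite values in marker ", nm)
    if (r[1] == r[2]) {
      stop("marker '", nm, "' is constant; min-max normalization undefined")
    }
    (v - r[1]) / (r[2] - r[1])
  }
  if (is.null(dim(x))) return(scale1(x, deparse(substitute(x))))
  for (j in seq_len(ncol(x))) {
    x[, j] <- scale1(x[, j], colnames(x)[j] %||% j)
  }
  x
}

#' Assemble the regression feature table for one day
#'
#' Normalized marker concentrations on the given day plus the binary
#' outcome, for every successful draw (the binary outcome is defined for
#' all of them, including draws the four-way classification excludes).
#'
#' @param cohort A `cohort`.
#' @param labels Labels from [label_cohort()].
#' @param day Day whose concentrations are used as predictors.
#' @param markers Marker states (must be in the screened set).
#' @return data.frame `draw_id`, one normalized column per marker,
#'   `outcome` (factor normal/pathological).
#' @export
feature_table <- function(cohort, labels, day, markers) {
  stopifnot(inherits(cohort, "cohort"))
  bad <- setdiff(markers, cohort$marker_roles$screened)
  if (length(bad)) {
    stop("markers not in the screened set: ", paste(bad, collapse = ", "))
  }
  ids <- as.integer(rownames(cohort$trajectories))
  X <- matrix(cohort$trajectories[, day, markers], ncol = length(markers),
              dimnames = list(NULL, markers))
  out <- data.frame(draw_id = ids, normalize_minmax(X))
  out$outcome <- labels$binary[match(ids, labels$draw_id)]
  stopifnot(!anyNA(out$outcome))
  out
}

#' Maximum-likelihood logistic regression
#'
#' Thin wrapper around [stats::glm()] (binomial family, IRLS, convergence
#' tolerance 1e-8) returning the pieces the panel evaluation needs.
#' Complete or quasi-complete separation is detected from fitted
#' probabilities pinned to 0/1 and reported via `separation = TRUE`
#' (coefficients are then diverging and their magnitudes meaningless);
#' a single-class outcome is an error.
#'
#' @param X Numeric matrix/data.frame of predictors (columns named).
#' @param y Binary outcome (factor with positive class second, or 0/1).
#' @return List `coefficients` (named, without intercept), `intercept`,
#'   `odds_ratios`, `fitted` (probabilities), `converged`, `separation`,
#'   `deviance`, `model` (the glm fit).
#' @export
fit_logistic <- function(X, y) {
  y01 <- as_binary01(y)
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X) + 1) {
    stop("need more observations than predictors + 1")
  }
  df <- data.frame(X, .y = y01)
  # near-separation is detected and flagged below; muffle glm's warning
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  probs <- stats::fitted(fit)
  sep <- any(probs > 1 - 1e-8 & y01 == 1) && any(probs < 1e-8 & y01 == 0) &&
    max(abs(stats::coef(fit)[-1])) > 15
  cf <- stats::coef(fit)
  list(coefficients = cf[-1], intercept = unname(cf[1]),
       odds_ratios = exp(cf[-1]), fitted = as.numeric(probs),
       converged = fit$converged, separation = isTRUE(sep),
       deviance = stats::deviance(fit), model = fit)
}

#' Stratified tenfold cross-validation of a logistic panel
#'
#' Splits the draws into `k` outcome-stratified folds (fold sizes differing
#' by at most 1 within each class), refits the logistic model on each
#' training set, and pools the out-of-fold predicted probabilities into a
#' single vector on which one ROC curve and AUC are computed. The fold
#' assignment is a deterministic function of `seed`.
#'
#' @inheritParams fit_logistic
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @return List `auc`, `ci`, `probs` (pooled out-of-fold, in input order),
#'   `folds` (fold id per observation), `k`.
#' @export
cross_validate <- function(X, y, k = 10, seed = 1) {
  y01 <- as_binary01(y)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= k)
  if (min(table(y01)) < k) {
    stop("stratified ", k, "-fold CV needs at least ", k,
         " observations in each class")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  folds <- integer(n)
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y01 == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  probs <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- fit_logistic(X[!test, , drop = FALSE], y01[!test])
    eta <- cbind(1, X[test, , drop = FALSE]) %*%
      c(fit$intercept, fit$coefficients)
    probs[test] <- stats::plogis(as.numeric(eta))
  }
  ci <- auc_ci(probs, y01)
  list(auc = ci$auc, ci = ci$ci, probs = probs, folds = folds, k = k)
}

marker_panels <- function(markers) {
  panels <- list()
  for (size in seq_along(markers)) {
    cmb <- utils::combn(markers, size, simplify = FALSE)
    panels <- c(panels, cmb)
  }
  names(panels) <- vapply(panels, paste, "", collapse = "+")
  panels
}

#' Evaluate biomarker panels with logistic regression and ROC analysis
#'
#' For each requested day, fits one logistic regression per non-empty
#' subset of the markers (3 singles, 3 pairs, 1 triple for the default
#' three-marker set), derives each panel's ROC curve, AUC and DeLong 95%
#' confidence interval, runs the DeLong paired test on every pair of
#' panels (21 comparisons for 7 panels; p-values are reported raw, without
#' multiplicity correction), and cross-validates the full-panel model with
#' stratified tenfold CV. All fits use the binary outcome over every
#' successful draw.
#'
#' @inheritParams feature_table
#' @param days Days whose marker concentrations are evaluated (default
#'   c(14, 21)).
#' @param markers Marker states; defaults to the IL-10, TIMP-1 and
#'   fibronectin analogs of the reference model when present.
#' @param cv_folds Folds for the cross-validation (default 10).
#' @param seed Seed for the CV fold assignment.
#' @return List of class `panel_evaluation`, one element per day, each with
#'   `panels` (per panel: `markers`, `coefficients`, `intercept`,
#'   `odds_ratios`, `auc`, `ci`, `roc`, `deviance`, `separation`),
#'   `comparisons` (data.frame `panel_a`, `panel_b`, `auc_a`, `auc_b`, `z`,
#'   `p`), and `cv` (for the full panel: `auc`, `ci`).
#' @export
evaluate_panels <- function(cohort, labels, days = c(14, 21),
                            markers = NULL, cv_folds = 10, seed = 1) {
  if (is.null(markers)) {
    markers <- intersect(c("I10", "T1", "FN"),
                         cohort$marker_roles$screened)
    if (length(markers) != 3) {
      stop("pass `markers`: this model has no default prognostic trio")
    }
  }
  panels <- marker_panels(markers)
  result <- lapply(days, function(day) {
    feats <- feature_table(cohort, labels, day, markers)
    y <- feats$outcome
    fitted_panels <- lapply(panels, function(mk) {
      fit <- fit_logistic(feats[, mk, drop = FALSE], y)
      ci <- auc_ci(fit$fitted, y)
      list(markers = mk, coefficients = fit$coefficients,
           intercept = fit$intercept, odds_ratios = fit$odds_ratios,
           auc = ci$auc, ci = ci$ci, roc = roc_curve(fit$fitted, y),
           deviance = fit$deviance, separation = fit$separation,
           fitted = fit$fitted)
    })
    pn <- names(panels)
    pairs <- utils::combn(seq_along(pn), 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      dt <- delong_test(fitted_panels[[a]]$fitted,
                        fitted_panels[[b]]$fitted, y)
      data.frame(panel_a = pn[a], panel_b = pn[b],
                 auc_a = dt$auc_a, auc_b = dt$auc_b, z = dt$z, p = dt$p,
                 stringsAsFactors = FALSE)
    }))
    full <- pn[length(pn)]
    cv <- cross_validate(feats[, panels[[full]], drop = FALSE], y,
                         k = cv_folds, seed = seed)
    list(day = day, panels = fitted_panels, comparisons = comparisons,
         cv = list(panel = full, auc = cv$auc, ci = cv$ci))
  })
  names(result) <- paste0("day", days)
  structure(result, class = "panel_evaluation", markers = markers)
}

#' Flatten a panel evaluation into a tidy AUC table
#'
#' @param evaluation A `panel_evaluation`.
#' @return data.frame `day`, `panel`, `n_markers`, `auc`, `ci_lo`, `ci_hi`.
#' @export
panel_auc_table <- function(evaluation) {
  do.call(rbind, lapply(evaluation, function(dayres) {
    do.call(rbind, lapply(names(dayres$panels), function(pn) {
      p <- dayres$panels[[pn]]
      data.frame(day = dayres$day, panel = pn,
                 n_markers = length(p$markers), auc = p$auc,
                 ci_lo = p$ci[1], ci_hi = p$ci[2],
                 stringsAsFactors = FALSE)
    }))
  }))
}
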