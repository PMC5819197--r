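test_that("histogram fractions are equal-width occupancy fractions", {
  h <- conc_histogram(c(1, 2, 3, 4), n_bins = 4, range = c(1, 4 + 1e-9))
  expect_equal(h$fractions, rep(0.25, 4))
  expect_length(h$bin_edges, 5)
  expect_true(all(diff(h$bin_edges) > 0))
})

test_that("histogram fractions always sum to one", {
  set.seed(2)
  for (i in 1:20) {
    vals <- stats::rnorm(stats::rpois(1, 50) + 1)
    h <- conc_histogram(vals)
    expect_equal(sum(h$fractions), 1, tolerance = 1e-12)
  }
})

test_that("degenerate single-valued input occupies one bin after widening", {
  h <- conc_histogram(rep(3.7, 10))
  expect_equal(sum(h$fractions), 1)
  expect_identical(sum(h$fractions > 0), 1L)
})

test_that("out-of-range values are an error, not silently dropped", {
  expect_error(conc_histogram(c(1, 5), range = c(0, 4)), "outside")
})

test_that("Bhattacharyya coefficient worked examples", {
  edges <- seq(0, 3, length.out = 4)
  mk <- function(fr) structure(list(bin_edges = edges, fractions = fr,
                                    n = 10), class = "conc_histogram")
  expect_equal(bhattacharyya(mk(c(0.5, 0.5, 0)), mk(c(0.5, 0.5, 0))), 1)
  expect_equal(bhattacharyya(mk(c(1, 0, 0)), mk(c(0, 0, 1))), 0)
  expect_equal(bhattacharyya(mk(c(0.5, 0.5, 0)), mk(c(0, 0.5, 0.5))), 0.5)
})

test_that("identical distributions give BC = 1 exactly", {
  set.seed(31)
  vals <- stats::rlnorm(500)
  h <- conc_histogram(vals)
  expect_equal(bhattacharyya(h, h), 1, tolerance = 1e-12)
})

test_that("BC is symmetric and within [0, 1] on random histogram pairs", {
  set.seed(13)
  edges <- seq(-1, 1, length.out = 51)
  for (i in 1:1000) {
    p <- stats::rgamma(50, 0.5); p <- p / sum(p)
    q <- stats::rgamma(50, 0.5); q <- q / sum(q)
    h1 <- structure(list(bin_edges = edges, fractions = p, n = 1),
                    class = "conc_histogram")
    h2 <- structure(list(bin_edges = edges, fractions = q, n = 1),
                    class = "conc_histogram")
    bc <- bhattacharyya(h1, h2)
    expect_gte(bc, 0)
    expect_lte(bc, 1)
    expect_equal(bc, bhattacharyya(h2, h1), tolerance = 1e-14)
  }
})

test_that("BC requires shared bin edges", {
  h1 <- conc_histogram(1:10, range = c(0, 11))
  h2 <- conc_histogram(1:10, range = c(0, 12))
  expect_error(bhattacharyya(h1, h2), "identical bin edges")
})

test_that("BC is invariant under common rescaling of both samples", {
  set.seed(17)
  a <- stats::rlnorm(400); b <- stats::rlnorm(400, 0.5)
  bc_at_scale <- function(s) {
    r <- range(c(a, b)) * s
    bhattacharyya(conc_histogram(a * s, range = r),
                  conc_histogram(b * s, range = r))
  }
  expect_equal(bc_at_scale(1), bc_at_scale(137.5), tolerance = 1e-12)
})

test_that("BC is stable under bin refinement for smooth samples", {
  set.seed(23)
  a <- stats::rnorm(2000); b <- stats::rnorm(2000, 0.6)
  r <- range(c(a, b))
  bc50 <- bhattacharyya(conc_histogram(a, 50, r), conc_histogram(b, 50, r))
  bc100 <- bhattacharyya(conc_histogram(a, 100, r),
                         conc_histogram(b, 100, r))
  expect_lt(abs(bc50 - bc100), 0.05)
})

test_that("overlap reduction formula and conventions", {
  expect_equal(overlap_reduction(0.8, 0.5), 37.5)
  expect_equal(overlap_reduction(0.6, 0.6), 0)
  expect_lt(overlap_reduction(0.5, 0.7), 0)
  expect_true(is.na(overlap_reduction(0, 0.1)))
})

test_that("screen ranks separated proteins first and overlapping last", {
  # hand-built cohort: among screened proteins, SEP separates the groups
  # completely, OVR is identically distributed in all groups
  n <- 60
  states <- c("F", "SEP", "OVR", "COL")
  traj <- array(0, dim = c(n, 40, 4),
                dimnames = list(1:n, 1:40, states))
  cls <- rep(c("normal", "mild", "severe"), each = n / 3)
  set.seed(41)
  traj[, 7, "SEP"] <- c(stats::runif(20, 0, 1), stats::runif(20, 2, 3),
                        stats::runif(20, 4, 5))
  traj[, 7, "OVR"] <- rep(stats::runif(20, 0, 1), 3)
  coh <- structure(
    list(model_name = "toy",
         marker_roles = list(collagen = "COL", fibroblast = "F",
                             screened = c("SEP", "OVR")),
         reference = NULL, draws = matrix(0, n, 1),
         trajectories = traj,
         failures = data.frame(draw_id = integer(0),
                               reason = character(0)),
         horizon = 40),
    class = "cohort")
  labels <- data.frame(
    draw_id = 1:n,
    class4 = factor(cls, levels = c("normal", "mild", "severe",
                                    "excluded")),
    binary = factor(ifelse(cls == "severe", "pathological", "normal"),
                    levels = c("normal", "pathological")))
  scr <- screen_overlap(coh, labels, days = 7)
  rk <- scr$ranking
  expect_identical(rk$protein[rk$rank == 1], "SEP")
  expect_identical(rk$protein[rk$rank == 2], "OVR")
  expect_equal(rk$mean_bc[rk$protein == "SEP"], 0)
  expect_equal(rk$mean_bc[rk$protein == "OVR"], 1, tolerance = 1e-12)
  expect_error(screen_overlap(coh, labels, days = 7, proteins = "COL"),
               "screened")
})

test_that("excluded draws never enter the screening histograms", {
  coh <- small_cohort()
  lab <- label_cohort(coh)
  scr <- screen_overlap(coh, lab, days = 40)
  counts <- table(lab$class4)
  expect_true(all(scr$overlaps$n_normal == counts[["normal"]]))
  expect_setequal(
    scr$overlaps$n_path[scr$overlaps$pair == "normal_vs_mild"],
    counts[["mild"]])
})
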