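test_that("AUC worked examples", {
  # positives {0.9, 0.4}, negatives {0.8, 0.2}: 3 of 4 pairs concordant
  scores <- c(0.9, 0.4, 0.8, 0.2)
  labels <- c(1, 1, 0, 0)
  expect_equal(roc_auc(scores, labels), 0.75)
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
})

test_that("AUC equals exhaustive concordant-pair counting", {
  brute_auc <- function(pos, neg) {
    s <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(s)
  }
  set.seed(19)
  for (i in 1:200) {
    m <- sample(2:30, 1); n <- sample(2:30, 1)
    pos <- sample(stats::rnorm(m), m)   # continuous
    neg <- stats::rnorm(n)
    if (i %% 3 == 0) {                  # force heavy ties
      pos <- sample(0:3, m, replace = TRUE)
      neg <- sample(0:3, n, replace = TRUE)
    }
    expect_equal(roc_auc(c(pos, neg), rep(c(1, 0), c(m, n))),
                 brute_auc(pos, neg), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(29)
  scores <- stats::rnorm(200)
  y <- stats::rbinom(200, 1, 0.4)
  a0 <- roc_auc(scores, y)
  expect_equal(roc_auc(exp(scores), y), a0, tolerance = 1e-12)
  expect_equal(roc_auc(stats::qlogis(stats::plogis(scores)), y), a0,
               tolerance = 1e-10)
})

test_that("ROC curve is a proper monotone curve whose area equals the AUC", {
  set.seed(37)
  scores <- round(stats::rnorm(150), 1)   # include ties
  y <- stats::rbinom(150, 1, 0.35)
  rc <- roc_curve(scores, y)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
  trap <- sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) +
                                utils::tail(rc$tpr, -1)) / 2)
  expect_equal(trap, roc_auc(scores, y), tolerance = 1e-12)
})

test_that("AUC and DeLong CI agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  scores <- stats::rnorm(300) + 0.8 * stats::rbinom(300, 1, 0.5)
  y <- as.integer(scores + stats::rnorm(300) > 0.5)
  r <- suppressMessages(pROC::roc(y, scores, direction = "<"))
  expect_equal(roc_auc(scores, y), as.numeric(pROC::auc(r)),
               tolerance = 1e-12)
  ours <- auc_ci(scores, y)
  theirs <- suppressMessages(as.numeric(pROC::ci.auc(r, method = "delong")))
  expect_equal(ours$ci[1], theirs[1], tolerance = 1e-9)
  expect_equal(ours$ci[2], theirs[3], tolerance = 1e-9)
})

test_that("degenerate separation collapses the CI and is flagged", {
  out <- auc_ci(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_true(out$degenerate)
  expect_equal(out$ci, c(1, 1))
})

test_that("DeLong interval covers the null AUC at close to nominal rate", {
  set.seed(53)
  hits <- 0L
  for (i in 1:1000) {
    scores <- stats::rnorm(1000)
    y <- rep(c(0, 1), 500)
    ci <- auc_ci(scores, y)$ci
    if (ci[1] <= 0.5 && ci[2] >= 0.5) hits <- hits + 1L
  }
  expect_gte(hits / 1000, 0.93)
})

test_that("DeLong variance agrees with a stratified bootstrap", {
  set.seed(59)
  pos <- stats::rnorm(200, 0.6)
  neg <- stats::rnorm(200)
  scores <- c(pos, neg); y <- rep(c(1, 0), c(200, 200))
  v_delong <- auc_ci(scores, y)$var
  boot <- replicate(2000, {
    roc_auc(c(sample(pos, replace = TRUE), sample(neg, replace = TRUE)), y)
  })
  expect_lt(abs(v_delong - stats::var(boot)) / stats::var(boot), 0.15)
})

test_that("DeLong paired test conventions", {
  set.seed(61)
  scores <- stats::rnorm(100)
  y <- rep(c(0, 1), 50)
  self <- delong_test(scores, scores, y)
  expect_equal(self$diff, 0)
  expect_equal(self$p, 1)
  b <- scores + stats::rnorm(100, sd = 0.4)
  ab <- delong_test(scores, b, y)
  ba <- delong_test(b, scores, y)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
})

test_that("DeLong test p-value matches pROC on a paired comparison", {
  skip_if_not_installed("pROC")
  set.seed(67)
  x <- stats::rnorm(250); latent <- x + stats::rnorm(250)
  y <- as.integer(latent > 0)
  s1 <- x + stats::rnorm(250, sd = 0.8)
  s2 <- x + stats::rnorm(250, sd = 1.2)
  ours <- delong_test(s1, s2, y)
  r1 <- suppressMessages(pROC::roc(y, s1, direction = "<"))
  r2 <- suppressMessages(pROC::roc(y, s2, direction = "<"))
  theirs <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  expect_equal(ours$p, as.numeric(theirs$p.value), tolerance = 1e-9)
})
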