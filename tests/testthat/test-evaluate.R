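test_that("AUROC equals the pairwise probability with ties at one half", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auroc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(auroc(c(5, 5, 5, 5), c(0, 1, 0, 1)), 0.5)  # all tied
  expect_error(auroc(1:4, rep(1, 4)), "both classes")
  # null value on independent scores
  set.seed(1)
  expect_equal(auroc(runif(10000), rbinom(10000, 1, 0.3)), 0.5,
               tolerance = 0.02 / 0.5)
})

test_that("AUROC and AUPRC match brute force on exhaustive small cases", {
  set.seed(71)
  for (rep_i in 1:60) {
    n <- sample(3:8, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes present
    ties <- sample(c(TRUE, FALSE), 1)
    scores <- if (ties) sample(seq(0, 1, 0.25), n, replace = TRUE)
    else runif(n)
    expect_equal(auroc(scores, labels), auroc_brute(scores, labels))
    expect_equal(auprc(scores, labels), auprc_brute(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly increasing transforms", {
  set.seed(2)
  scores <- rnorm(300)
  labels <- rbinom(300, 1, plogis(scores))
  a <- auroc(scores, labels)
  expect_equal(auroc(plogis(scores), labels), a)
  expect_equal(auroc(exp(scores), labels), a)
  expect_equal(auroc(rank(scores), labels), a)
})

test_that("PR analysis behaves at the boundaries and annotates thresholds", {
  # perfect classifier
  expect_equal(auprc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  # random scores at prevalence q -> AUPRC near q
  set.seed(3)
  q <- 0.1
  scores <- runif(20000)
  labels <- rbinom(20000, 1, q)
  expect_equal(auprc(scores, labels), q, tolerance = 0.015 / q)
  expect_error(pr_curve(1:3, c(0, 0, 0)), "positive")
  pc <- pr_curve(c(0.9, 0.7, 0.5, 0.3), c(1, 0, 1, 0), annotate_at = 0.5)
  expect_equal(pc$annotations$threshold, 0.5)
  expect_equal(pc$annotations$recall, 1)
  expect_equal(pc$annotations$precision, 2 / 3)
})

test_that("sensitivity-floor threshold matches exhaustive enumeration", {
  # worked example: largest threshold reaching sensitivity 0.95
  r <- threshold_for_sensitivity(c(0.9, 0.8, 0.2, 0.5, 0.1),
                                 c(1, 1, 1, 0, 0), 0.95)
  expect_equal(r$threshold, 0.2)
  expect_equal(r$specificity, 0.5)
  # perfectly separated data keeps specificity 1
  r2 <- threshold_for_sensitivity(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), 0.95)
  expect_equal(r2$specificity, 1)
  # vacuous constraint
  r3 <- threshold_for_sensitivity(c(0.3, 0.6), c(1, 0), 0)
  expect_equal(r3$threshold, Inf)
  expect_equal(r3$specificity, 1)
  # randomized agreement with the brute-force oracle (with ties)
  set.seed(19)
  for (i in 1:40) {
    n <- sample(6:25, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    for (ms in c(0.5, 0.8, 0.95, 1)) {
      got <- threshold_for_sensitivity(scores, labels, ms)
      want <- spec_at_sens_brute(scores, labels, ms)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$specificity, want$specificity)
      expect_gte(got$sensitivity, ms)
    }
  }
})

test_that("Brier score and skill follow their closed forms", {
  expect_equal(brier(c(1, 0, 1), c(1, 0, 1)), 0)
  q <- 0.0089
  set.seed(4)
  y <- rbinom(500000, 1, q)
  # constant p on outcomes with prevalence q: q(1-p)^2 + (1-q)p^2
  p <- q
  expect_equal(brier(rep(p, length(y)), y),
               mean(y) * (1 - p)^2 + (1 - mean(y)) * p^2, tolerance = 1e-12)
  expect_equal(q * (1 - q)^2 + (1 - q) * q^2, 0.00882, tolerance = 5e-4 / 0.00882)
  expect_error(brier(c(0.5, 1.2), c(0, 1)), "0, 1")
  # skill score
  expect_equal(brier_skill(0.1, 0.1), 0)
  expect_equal(brier_skill(0, 0.1), 1)
  expect_equal(brier_skill(0.0089, 0.0178), 0.5)
  expect_error(brier_skill(0.1, 0), "positive")
})

test_that("calibration curve collapses for a constant predictor and marks p99", {
  set.seed(5)
  q <- 0.3
  y <- rbinom(2000, 1, q)
  cal <- calibration_curve(rep(q, 2000) + runif(2000, -1e-9, 1e-9), y)
  expect_equal(mean(cal$curve$observed), q, tolerance = 0.05 / q)
  expect_lt(diff(range(cal$curve$predicted)), 1e-6)
  p <- runif(5000)
  cal2 <- calibration_curve(p, rbinom(5000, 1, p))
  expect_equal(cal2$percentile_99, quantile(p, 0.99), ignore_attr = TRUE)
  expect_true(all(cal2$curve$observed >= 0 & cal2$curve$observed <= 1))
  expect_error(calibration_curve(runif(10), rbinom(10, 1, 0.5)), "n >= 50")
})

test_that("bootstrap evaluation is paired, deterministic and self-consistent", {
  set.seed(6)
  n <- 400
  labels <- rbinom(n, 1, 0.15)
  good <- plogis(qlogis(0.15) + 2 * labels + rnorm(n))
  same <- good
  rand <- runif(n)
  rep1 <- bootstrap_evaluate(list(A = good, B = same, C = rand), labels,
                             n_boot = 200, seed = 11)
  rep2 <- bootstrap_evaluate(list(A = good, B = same, C = rand), labels,
                             n_boot = 200, seed = 11)
  expect_identical(rep1$metrics, rep2$metrics)
  # identical score vectors: paired differences exactly zero, not significant
  ab <- rep1$comparisons[rep1$comparisons$model_a == "A" &
                           rep1$comparisons$model_b == "B"]
  expect_equal(ab$diff_median, 0)
  expect_equal(ab$ci_low, 0)
  expect_equal(ab$ci_high, 0)
  expect_false(ab$significant)
  # medians fall inside their own percentile intervals
  m <- rep1$metrics
  expect_true(all(m$ci_low <= m$median + 1e-12 &
                    m$median <= m$ci_high + 1e-12, na.rm = TRUE))
  # per-replicate sensitivity respects the floor by construction
  expect_true(all(rep1$boot[, , "sensitivity"] >= 0.95))
})

test_that("strongly separated models yield a significant AUROC difference", {
  set.seed(7)
  n <- 2000
  labels <- rbinom(n, 1, 0.1)
  strong <- labels * 2 + rnorm(n)      # true AUROC ~ 0.92
  weak <- runif(n)                     # AUROC ~ 0.5
  rep <- bootstrap_evaluate(list(strong = strong, weak = weak), labels,
                            n_boot = 500, seed = 12)
  cmp <- rep$comparisons
  expect_true(cmp$significant)
  expect_gt(cmp$ci_low, 0)
})

test_that("single-class bootstrap replicates are redrawn, keeping n_boot", {
  set.seed(8)
  labels <- c(1, rep(0, 60))  # single positive: redraws will occur
  scores <- runif(61)
  expect_message(
    rep <- bootstrap_evaluate(list(m = scores), labels, n_boot = 100,
                              seed = 3),
    "redrawn")
  expect_equal(sum(!is.na(rep$boot[, 1, "auroc"])), 100L)
  expect_gt(rep$redraws, 0L)
})
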