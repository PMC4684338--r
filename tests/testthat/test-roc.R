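test_that("perfectly separated scores give AUC 1 and a threshold between groups", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- rep(c("SC", "SF"), each = 3)
  roc <- rocAnalysis(scores, labels, positive = "SF")
  expect_equal(roc$auc, 1)
  expect_true(roc$threshold > 3 && roc$threshold < 10)
  expect_equal(roc$sensitivity, 1)
  expect_equal(roc$specificity, 1)
})

test_that("rank AUC equals the trapezoidal area under the empirical curve", {
  set.seed(55)
  for (i in 1:10) {
    scores <- rnorm(40)
    labels <- sample(rep(c("SF", "SC"), each = 20))
    roc <- rocAnalysis(scores, labels, positive = "SF")
    cv <- roc$curve[order(1 - roc$curve$specificity, roc$curve$sensitivity), ]
    x <- 1 - cv$specificity; y <- cv$sensitivity
    area <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
    expect_equal(roc$auc, area, tolerance = 1e-12)
  }
})

test_that("AUC and DeLong CI agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(66)
  co <- generateCohort(CohortSpec(seed = 66))
  roc <- rocAnalysis(co$pct_augc, co$outcome, positive = "SF")
  ref <- pROC::roc(co$outcome, co$pct_augc, levels = c("SC", "SF"),
                   direction = "<", quiet = TRUE)
  expect_equal(roc$auc, as.numeric(ref$auc), tolerance = 1e-12)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(ref, method = "delong")))
  expect_equal(roc$ci_low, max(ci[1], 0), tolerance = 1e-6)
  expect_equal(roc$ci_high, min(ci[3], 1), tolerance = 1e-6)
  # Youden-optimal threshold matches the reference "best" coordinate
  best <- pROC::coords(ref, "best", best.method = "youden",
                       transpose = FALSE)
  expect_equal(roc$sensitivity, best$sensitivity[1], tolerance = 1e-9)
  expect_equal(roc$specificity, best$specificity[1], tolerance = 1e-9)
})

test_that("labels shuffled independently of scores give AUC near 1/2", {
  set.seed(77)
  aucs <- vapply(seq_len(300), function(i) {
    scores <- rnorm(30)
    labels <- sample(rep(c("SF", "SC"), times = c(14, 16)))
    rocAnalysis(scores, labels, positive = "SF")$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("direction '<' mirrors the analysis of a protective marker", {
  scores <- c(10, 11, 12, 1, 2, 3)
  labels <- rep(c("SC", "SF"), each = 3)
  roc <- rocAnalysis(scores, labels, positive = "SF", direction = "<")
  expect_equal(roc$auc, 1)
  expect_true(roc$threshold > 3 && roc$threshold < 10)
  expect_error(rocAnalysis(1:5, rep("SF", 5)), "both outcome classes")
})

test_that("a threshold rule reproduces its own confusion table", {
  co <- generateCohort(CohortSpec(seed = 12))
  perf <- thresholdPerformance(co$pct_augc, co$outcome, 19.78,
                               positive = "SF")
  tab <- perf$table
  expect_equal(tab$tp + tab$fn, sum(co$outcome == "SF"))
  expect_equal(tab$tn + tab$fp, sum(co$outcome == "SC"))
  expect_equal(tab$sensitivity, 100 * tab$tp / (tab$tp + tab$fn))
})
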