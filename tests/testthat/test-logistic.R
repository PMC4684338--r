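test_that("a constant predictor gives the null odds ratio", {
  y <- rep(c("SF", "SC"), each = 10)
  res <- univariateLogistic(rep(3.3, 20), y)
  expect_equal(res$coefficient, 0)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_value, 1)
})

test_that("the odds ratio points in the direction of the group shift", {
  # SF sites have systematically higher percent change in AUGC
  co <- generateCohort(CohortSpec(nSF = 2000, nSC = 2000, seed = 17))
  res <- univariateLogistic(co$pct_augc, co$outcome, positive = "SF")
  expect_gt(res$odds_ratio, 1)
  expect_lt(res$p_value, 1e-6)
  expect_true(res$ci_low <= res$odds_ratio && res$odds_ratio <= res$ci_high)
  expect_equal(res$odds_ratio, exp(res$coefficient))
})

test_that("complete separation is flagged with an unbounded CI", {
  x <- c(rnorm(15, -5), rnorm(15, 5))
  y <- rep(c(0, 1), each = 15)
  res <- suppressWarnings(univariateLogistic(x, y))
  expect_true(res$separation)
  expect_equal(res$ci_high, Inf)
})

test_that("input guards: small n and single-class outcomes are errors", {
  expect_error(univariateLogistic(rnorm(5), rep(c(0, 1), len = 5)), "at least 10")
  expect_error(univariateLogistic(rnorm(12), rep(1, 12)), "both outcome classes")
})

test_that("a strong single candidate is selected and keeps its sign when adjusted", {
  set.seed(41)
  n <- 120
  x <- rnorm(n)
  z <- rnorm(n)                       # confounder, mildly associated
  y <- rbinom(n, 1, plogis(1.5 * x + 0.3 * z))
  df <- data.frame(x = x, z = z, noise = rnorm(n), outcome = y)
  sel <- stepwiseMultivariate(df, candidates = c("x", "noise"),
                              outcome = "outcome", confounders = "z",
                              positive = "1")
  expect_equal(sel$selected, "x")
  expect_gt(sel$adjusted$odds_ratio[sel$adjusted$term == "x"], 1)
})

test_that("of two collinear candidates exactly one survives selection", {
  set.seed(42)
  n <- 150
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.2 * x))
  df <- data.frame(a = x, b = x, outcome = y)  # duplicated predictor
  sel <- stepwiseMultivariate(df, candidates = c("a", "b"),
                              outcome = "outcome", positive = "1")
  expect_length(sel$selected, 1)
})

test_that("all-noise candidates can produce an empty selection without error", {
  set.seed(43)
  n <- 100
  df <- data.frame(a = rnorm(n), b = rnorm(n), outcome = rbinom(n, 1, 0.5))
  sel <- stepwiseMultivariate(df, candidates = c("a", "b"),
                              outcome = "outcome", positive = "1")
  expect_true(length(sel$selected) %in% c(0, 1))  # usually empty under the null
  expect_s3_class(sel$adjusted, "data.frame")
})

test_that("numeric outcomes must be coded 0/1", {
  expect_error(univariateLogistic(rnorm(12), rep(c(1, 2), 6)), "0/1")
})
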