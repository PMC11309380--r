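smallConfig <- function(...) {
  experimentConfig(n_samples = 300, n_shuffles = 4, min_support = 4, ...)
}

test_that("perfect predictors make both frameworks perfect", {
  perfect <- lapply(allModelIds(), function(m) predictorSpec(m, 1, 1))
  res <- runExperiment(smallConfig(predictors = perfect), seed = 1)
  ag <- aggregateReport(res)
  expect_equal(ag$single$sensitivity_low[["mean"]], 100)
  expect_equal(ag$single$sensitivity_high[["mean"]], 100)
  expect_equal(ag$single$specificity_low[["mean"]], 100)
  expect_equal(ag$boosted$sensitivity_low[["mean"]], 100)
  expect_equal(ag$boosted$sensitivity_high[["mean"]], 100)
  expect_equal(ag$boosted$specificity_low_pooled, 100)
  expect_equal(ag$boosted$specificity_high_pooled, 100)
})

test_that("experiments are deterministic under config + seed", {
  cfg <- smallConfig(rules = list(
    plantedRule(c("D_f", "S_f"), c("high", "high"), "high")))
  a <- runExperiment(cfg, seed = 5)
  b <- runExperiment(cfg, seed = 5)
  expect_identical(aggregateReport(a), aggregateReport(b))
  expect_identical(patterns(minedPatterns(a)), patterns(minedPatterns(b)))
  expect_identical(sensitivitySupportCurve(a), sensitivitySupportCurve(b))
  c <- runExperiment(cfg, seed = 6)
  expect_false(identical(aggregateReport(a), aggregateReport(c)))
})

test_that("aggregate means equal the arithmetic mean of shuffles", {
  res <- runExperiment(smallConfig(), seed = 2)
  perShuffle <- vapply(res@shuffles, function(s) {
    s$single_analyte$sensitivity$l
  }, numeric(1))
  ag <- aggregateReport(res)
  expect_equal(ag$single$sensitivity_low[["mean"]], mean(perShuffle),
               tolerance = 1e-12)
  expect_equal(ag$single$sensitivity_low[["sd"]], sd(perShuffle),
               tolerance = 1e-12)
  # per-class CV error is 1 - sensitivity (as a proportion)
  expect_equal(ag$single$cv_error_low[["mean"]],
               mean(1 - perShuffle / 100), tolerance = 1e-12)
})

test_that("boosted specificity dominates single-analyte specificity", {
  cfg <- smallConfig(rules = list(
    plantedRule(c("D_f", "S_f"), c("high", "high"), "high"),
    plantedRule(c("D_f", "S_f"), c("low", "low"), "low")))
  res <- runExperiment(cfg, seed = 3)
  ag <- aggregateReport(res)
  expect_gt(nPatterns(minedPatterns(res)), 0)
  expect_equal(ag$boosted$specificity_low_pooled, 100)
  expect_equal(ag$boosted$specificity_high_pooled, 100)
  expect_gte(ag$boosted$specificity_low_pooled,
             ag$single$specificity_low[["mean"]])
  expect_gte(ag$boosted$specificity_high_pooled,
             ag$single$specificity_high[["mean"]])
})

test_that("held-out evaluation mode scores only the last shuffle", {
  cfg <- experimentConfig(n_samples = 300, n_shuffles = 4, min_support = 3,
                          honest_eval = TRUE,
                          rules = list(plantedRule(c("D_f", "S_f"),
                                                   c("low", "low"), "low")))
  res <- runExperiment(cfg, seed = 4)
  ag <- aggregateReport(res)
  expect_equal(ag$scored_shuffles, 4)
  expect_equal(minedPatterns(res)@nShuffles, 3L)
  expect_true(!is.null(res@shuffles[[4]]$boosted))
  expect_null(res@shuffles[[1]]$boosted)
  # out-of-sample specificity is measured, not guaranteed, here
  expect_true(is.finite(ag$boosted$specificity_low_pooled) ||
                is.na(ag$boosted$specificity_low_pooled))
})

test_that("invalid configurations fail before any computation", {
  expect_error(experimentConfig(n_samples = 5), "too small")
  expect_error(experimentConfig(min_support = 11), "min_support")
  expect_error(experimentConfig(correlation = 2), "semi-definite")
  expect_error(experimentConfig(n_shuffles = 1, honest_eval = TRUE),
               "at least two")
})
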