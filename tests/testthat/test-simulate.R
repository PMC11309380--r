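test_that("simulated concentrations respect printed bounds and means", {
  conc <- simulateConcentrations(1045, correlation = diag(5), seed = 1)
  specs <- defaultMetaboliteSpecs()
  for (m in metaboliteNames()) {
    expect_true(all(conc[[m]] >= specs[[m]]$min_conc))
    expect_true(all(conc[[m]] <= specs[[m]]$max_conc))
  }
  big <- simulateConcentrations(10000, correlation = diag(5), seed = 2)
  expect_lt(abs(mean(big$A) - 0.563), 0.02)
  expect_lt(abs(mean(big$S) - 0.511), 0.02)
})

test_that("concentration generator is deterministic under seed", {
  a <- simulateConcentrations(50, seed = 7)
  b <- simulateConcentrations(50, seed = 7)
  expect_identical(a, b)
  c <- simulateConcentrations(50, seed = 8)
  expect_false(identical(a, c))
  one <- simulateConcentrations(1, seed = 7)
  expect_equal(nrow(one), 1)
})

test_that("copula correlation is transmitted to the marginals", {
  R <- matrix(0.5, 5, 5); diag(R) <- 1
  conc <- simulateConcentrations(8000, correlation = R, seed = 3)
  emp <- cor(conc$A, conc$D, method = "spearman")
  target <- (6 / pi) * asin(0.5 / 2)   # Spearman rho of a Gaussian copula
  expect_lt(abs(emp - target), 0.05)
  expect_gt(cor(conc$A, conc$S, method = "spearman"), 0.3)
})

test_that("invalid generator configurations are rejected", {
  bad <- matrix(0.9, 5, 5); diag(bad) <- 1; bad[1, 2] <- -0.9
  expect_error(simulateConcentrations(10, correlation = bad),
               "symmetric")
  nonpsd <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(checkCorrelation <- metaboost:::checkCorrelation(nonpsd),
               "positive semi-definite")
  expect_error(simulateConcentrations(0), "n must be")
  expect_error(metaboliteSpec("A", 0.5, 0.4, 0.45), "min_conc < mean_conc")
})

test_that("perfect surrogate predictors reproduce the labels exactly", {
  conc <- simulateConcentrations(200, seed = 4)
  labels <- assignClasses(conc)
  perfect <- lapply(allModelIds(), function(m) predictorSpec(m, 1, 1))
  ps <- simulatePredictions(conc, labels, perfect, seed = 5)
  pred <- predictedClasses(ps)
  for (m in allModelIds()) {
    metab <- sub("_[fl]$", "", m)
    expect_identical(unname(pred[m, ]), labels[[metab]])
  }
})

test_that("surrogate predictors hit their per-class sensitivities", {
  conc <- simulateConcentrations(5000, seed = 6)
  labels <- assignClasses(conc)
  ps <- simulatePredictions(conc, labels, seed = 7)
  pred <- predictedClasses(ps)["A_f", ]
  truth <- labels$A
  empLow <- mean(pred[truth == "low"] == "low")
  empHigh <- mean(pred[truth == "high"] == "high")
  expect_lt(abs(empLow - 0.8352), 0.02)
  expect_lt(abs(empHigh - 0.8235), 0.02)
})

test_that("planted rules control the antecedent-truth association", {
  conc <- simulateConcentrations(1000, seed = 8)
  labels <- assignClasses(conc)
  rule <- plantedRule(c("D_f", "S_f"), c("high", "high"), "high")
  ps <- simulatePredictions(conc, labels, rules = list(rule), seed = 9)
  pred <- predictedClasses(ps)
  matched <- pred["D_f", ] == "high" & pred["S_f", ] == "high"
  # penetrance 1: every antecedent match is a true high sample,
  # coverage 1: every true high sample matches
  expect_true(all(labels$A[matched] == "high"))
  expect_true(all(matched[labels$A == "high"]))

  half <- plantedRule(c("D_f", "S_f"), c("high", "high"), "high",
                      coverage = 0.5)
  ps2 <- simulatePredictions(conc, labels, rules = list(half), seed = 10)
  pred2 <- predictedClasses(ps2)
  matched2 <- pred2["D_f", ] == "high" & pred2["S_f", ] == "high"
  expect_true(all(labels$A[matched2] == "high"))
  # coverage is exact: chance matches on uncovered highs are broken too
  frac <- mean(matched2[labels$A == "high"])
  expect_lt(abs(frac - 0.5), 0.005)
})

test_that("prediction simulation is reproducible and validates input", {
  conc <- simulateConcentrations(50, seed = 11)
  labels <- assignClasses(conc)
  a <- simulatePredictions(conc, labels, seed = 12)
  b <- simulatePredictions(conc, labels, seed = 12)
  expect_identical(predictedClasses(a), predictedClasses(b))
  bad <- defaultPredictorSpecs()
  bad[[1]]$model_id <- "X_f"
  expect_error(simulatePredictions(conc, labels, bad), "unknown model_id")
  expect_error(
    validateRulesErr <- metaboost:::validateRules(list(
      plantedRule("D_f", "high", "high"),
      plantedRule("D_f", "high", "low"))),
    "co-occur")
  expect_error(simulatePredictions(conc[1:10, ], labels[11:20, ]),
               "cover")
})
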