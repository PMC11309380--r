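test_that("pattern enumeration is exhaustive and duplicate-free", {
  expect_equal(nrow(enumeratePatterns("A_f")), 2)
  two <- enumeratePatterns(c("A_f", "D_f"))
  expect_equal(nrow(two), 8)   # 2 singletons x 2 + 1 pair x 4
  expect_setequal(
    two$assignment,
    c("A_f=low", "A_f=high", "D_f=low", "D_f=high",
      "A_f=low,D_f=low", "A_f=high,D_f=low",
      "A_f=low,D_f=high", "A_f=high,D_f=high"))
  expect_equal(anyDuplicated(two$assignment), 0)
  expect_error(enumeratePatterns(c("A_f", "A_f")), "distinct")
})

test_that("ternary codes round-trip through index and description", {
  withr::with_seed(4, {
    for (rep in 1:50) {
      idx <- sample(3^10 - 1, 1)
      p <- patternFromIndex(idx)
      expect_equal(patternIndex(p$members, p$classes), idx)
    }
  })
  expect_equal(patternIndex(c("D_f", "S_f"), c("high", "high")),
               2 * 3^1 + 2 * 3^4)
})

test_that("pattern matching is conjunctive", {
  row <- c(A_f = "low", D_f = "high", S_l = "high")
  expect_true(matchPattern(list(members = "A_f",
                                classes = c(A_f = "low")), row))
  expect_false(matchPattern(
    list(members = c("D_f", "S_l"),
         classes = c(D_f = "high", S_l = "low")), row))
  expect_error(matchPattern(list(members = "N_f",
                                 classes = c(N_f = "low")), row),
               "missing predictions")
  # random rows against an element-wise loop oracle
  withr::with_seed(5, {
    for (rep in 1:30) {
      row <- setNames(sample(c("low", "high"), 10, replace = TRUE),
                      allModelIds())
      p <- patternFromIndex(sample(3^10 - 1, 1))
      manual <- TRUE
      for (m in p$members) {
        if (row[[m]] != p$classes[[m]]) manual <- FALSE
      }
      expect_equal(matchPattern(p, row), manual)
    }
  })
})

test_that("mined patterns agree exactly with the brute-force oracle", {
  withr::with_seed(6, {
    seeds <- sample(10000, 25)
  })
  for (i in seq_along(seeds)) {
    k <- (i %% 4) + 1
    nsh <- (i %% 3) + 1
    tabs <- randomTables(k, nSamples = 5 + (seeds[i] %% 26), nsh,
                         seed = seeds[i])
    minSupport <- (i %% nsh) + 1
    mined <- minePatterns(tabs, minSupport = minSupport)
    oracle <- oracleMine(tabs, minSupport = minSupport)
    got <- minedAsList(mined)
    expect_equal(length(got), length(oracle))
    expect_equal(got, oracle)
  }
})

test_that("every mined pattern has complete specificity per shuffle", {
  tabs <- randomTables(4, 8, 3, seed = 99)
  mined <- minePatterns(tabs, minSupport = 1)
  expect_gt(nPatterns(mined), 0)
  pure <- mined@matchedLow == 0 | mined@matchedHigh == 0
  expect_true(all(pure))
  # direction consistency: implied class matches every nonzero shuffle
  p <- patterns(mined)
  lowHits <- colSums(mined@matchedLow > 0)
  highHits <- colSums(mined@matchedHigh > 0)
  expect_true(all(lowHits[p$implied_class == "high"] == 0))
  expect_true(all(highHits[p$implied_class == "low"] == 0))
  expect_error(minePatterns(tabs, minSupport = 4), "exceeds")
})

test_that("adding a member to a pattern never increases its matches", {
  tabs <- randomTables(5, 30, 1, seed = 7)
  pred <- predictedClasses(tabs[[1]])
  withr::with_seed(8, {
    for (rep in 1:20) {
      mids <- modelIds(tabs[[1]])
      size <- sample(1:4, 1)
      members <- sample(mids, size)
      classes <- setNames(sample(c("low", "high"), size, replace = TRUE),
                          members)
      extra <- sample(setdiff(mids, members), 1)
      bigger <- c(classes, setNames(sample(c("low", "high"), 1), extra))
      count <- function(cls) {
        sum(apply(pred, 2, function(col) {
          all(col[names(cls)] == cls)
        }))
      }
      expect_lte(count(bigger), count(classes))
    }
  })
})

test_that("perfect predictors yield the singleton fruit-A patterns", {
  conc <- simulateConcentrations(300, seed = 9)
  labels <- assignClasses(conc)
  perfect <- lapply(allModelIds(), function(m) predictorSpec(m, 1, 1))
  sp <- makeSplits(conc$sample_id, nShuffles = 3, seed = 10)
  tabs <- lapply(1:3, function(s) {
    ps <- simulatePredictions(conc, labels, perfect, seed = 11)
    ids <- sp$sample_id[sp$shuffle_id == s & sp$subset == "test"]
    ps[, match(ids, colnames(ps))]
  })
  mined <- minePatterns(tabs, minSupport = 3)
  p <- patterns(mined)
  lowSingleton <- p[p$assignment == "A_f=low", ]
  expect_equal(nrow(lowSingleton), 1)
  expect_equal(lowSingleton$implied_class, "low")
  col <- which(p$assignment == "A_f=low")
  expect_true(all(mined@sensitivity[, col] == 100))
})

test_that("boosting resolves matches, conflicts and abstentions", {
  pred <- rbind(A_f = c("low", "high", "high"),
                D_f = c("low", "high", "low"),
                E_f = c("low", "high", "high"))
  tab <- toyPredictionSet(pred, c("low", "high", "high"))
  mined <- minePatterns(list(tab), minSupport = 1)
  p <- patterns(mined)
  expect_true("A_f=low" %in% p$assignment[p$implied_class == "low"])
  expect_true("D_f=high" %in% p$assignment[p$implied_class == "high"])

  # on the mining samples themselves, boosted classes are the truths
  expect_identical(boostPredictions(tab, mined), c("low", "high", "high"))
  # an unseen row matching both a low- and a high-implying pattern
  expect_identical(
    boostPredictions(c(A_f = "low", D_f = "high", E_f = "high"), mined),
    "conflict")
  # a support filter stricter than any pattern's support forces abstention
  expect_identical(
    boostPredictions(c(A_f = "low", D_f = "low", E_f = "low"), mined,
                     minSupport = 2),
    "abstain")

  dec <- decidePick(c("high", "low", "abstain", "conflict"),
                    c("low", "low", "low", "high"))
  expect_identical(dec$decision,
                   c("Pick", "Do not Pick", "Do not Pick", "Pick"))
  expect_identical(dec$conflict, c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(dec$used_fallback, c(FALSE, FALSE, TRUE, TRUE))
  expect_error(decidePick("high", c("low", "low")), "equal length")
})
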