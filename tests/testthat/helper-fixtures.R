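# Fixture builders and independent brute-force oracles used across tests.

# PredictionSet from a models x samples character matrix and true fruit-A
# classes (other metabolites default to the A classes).
toyPredictionSet <- function(pred, trueA) {
  tc <- data.frame(A = trueA, D = trueA, E = trueA, N = trueA, S = trueA)
  PredictionSet(pred, tc)
}

# Random small prediction tables over the first k model ids.
randomTables <- function(k, nSamples, nShuffles, seed) {
  mids <- allModelIds()[seq_len(k)]
  withr::with_seed(seed, {
    lapply(seq_len(nShuffles), function(s) {
      pred <- matrix(sample(c("low", "high"), k * nSamples, replace = TRUE),
                     k, nSamples, dimnames = list(mids, NULL))
      toyPredictionSet(pred, sample(c("low", "high"), nSamples,
                                    replace = TRUE))
    })
  })
}

# Brute-force pattern miner: nested loops over every (subset, assignment)
# pattern and every sample. Independent of the package's vectorized path.
oracleMine <- function(tables, minSupport) {
  mids <- modelIds(tables[[1]])
  k <- length(mids)
  out <- list()
  for (idx in seq_len(3^k - 1)) {
    digits <- (idx %/% 3^(seq_len(k) - 1)) %% 3
    members <- mids[digits > 0]
    classes <- c("low", "high")[digits[digits > 0]]
    perShuffle <- lapply(tables, function(tab) {
      pred <- predictedClasses(tab)
      truth <- trueClasses(tab)
      nl <- 0L; nh <- 0L
      for (j in seq_len(ncol(pred))) {
        ok <- TRUE
        for (i in seq_along(members)) {
          if (pred[members[i], j] != classes[i]) { ok <- FALSE; break }
        }
        if (ok) {
          if (truth[j] == "low") nl <- nl + 1L else nh <- nh + 1L
        }
      }
      c(nl = nl, nh = nh)
    })
    nl <- vapply(perShuffle, `[[`, integer(1), "nl")
    nh <- vapply(perShuffle, `[[`, integer(1), "nh")
    if (any(nl > 0 & nh > 0)) next           # impure in some shuffle
    if (any(nl > 0) && any(nh > 0)) next     # direction flips
    support <- sum(nl + nh > 0)
    if (support < minSupport || support == 0) next
    out[[length(out) + 1]] <- list(
      index = idx,
      implied = if (any(nl > 0)) "low" else "high",
      support = support, nl = nl, nh = nh)
  }
  out
}

# O(n^2) reference NMS: per-sample greedy suppression with explicit loops.
oracleNMS <- function(boxes, confThreshold, iouThreshold) {
  boxes <- boxes[boxes$confidence >= confThreshold, , drop = FALSE]
  if (nrow(boxes) == 0) return(boxes)
  ord <- order(-boxes$confidence, seq_len(nrow(boxes)))
  boxes <- boxes[ord, , drop = FALSE]
  suppressed <- rep(FALSE, nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    if (suppressed[i]) next
    if (i == nrow(boxes)) break
    for (j in (i + 1):nrow(boxes)) {
      if (suppressed[j]) next
      if (boxes$class[j] != boxes$class[i]) next
      if (iou(boxes[i, ], boxes[j, , drop = FALSE]) > iouThreshold) {
        suppressed[j] <- TRUE
      }
    }
  }
  boxes[!suppressed, , drop = FALSE]
}

randomBoxes <- function(n, seed) {
  withr::with_seed(seed, {
    w <- runif(n, 0.05, 0.4)
    h <- runif(n, 0.05, 0.4)
    detectionBoxes(class = sample(c("low", "high"), n, replace = TRUE),
                   x_center = runif(n, 0.25, 0.75),
                   y_center = runif(n, 0.25, 0.75),
                   width = w, height = h,
                   confidence = round(runif(n), 3))
  })
}

# Canonical comparable form of a mined PatternSet.
minedAsList <- function(mined) {
  p <- patterns(mined)
  ord <- order(p$index)
  lapply(ord, function(i) list(
    index = p$index[i], implied = p$implied_class[i],
    support = p$support[i],
    nl = unname(mined@matchedLow[, i]),
    nh = unname(mined@matchedHigh[, i])))
}
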