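#' Pattern encoding
#'
#' A pattern is a non-empty subset of the model universe with one assigned
#' class (`low`/`high`) per member. Patterns are encoded as base-3 integers
#' ("ternary codes"): model `m` contributes digit 0 (not a member),
#' 1 (member assigned `low`) or 2 (member assigned `high`) at place
#' `3^(m-1)`, with models in [allModelIds()] order. Codes run from 1 to
#' `3^k - 1`; code 0 is the empty pattern and is never used.
#'
#' @param members Character vector of model ids.
#' @param classes Character vector of `"low"`/`"high"`, one per member (may
#'   be named by member).
#' @param modelIds The model universe; default [allModelIds()].
#' @return `patternIndex()`: the integer code. `patternFromIndex()`: a list
#'   with `members` and named `classes`.
#' @examples
#' patternIndex("A_f", "low")  # 1
#' patternFromIndex(2)$classes # A_f = "high"
#' @export
patternIndex <- function(members, classes, modelIds = allModelIds()) {
  pos <- match(members, modelIds)
  if (anyNA(pos)) stop("unknown model id in members", call. = FALSE)
  if (anyDuplicated(pos)) stop("duplicate members", call. = FALSE)
  digit <- match(classes, CLASS_LEVELS)
  if (anyNA(digit) || length(digit) != length(pos)) {
    stop("classes must be 'low'/'high', one per member", call. = FALSE)
  }
  sum(digit * 3^(pos - 1))
}

#' @rdname patternIndex
#' @param index Integer code in `1 .. 3^k - 1`.
#' @export
patternFromIndex <- function(index, modelIds = allModelIds()) {
  k <- length(modelIds)
  if (index < 1 || index > 3^k - 1) stop("index out of range", call. = FALSE)
  digits <- (index %/% 3^(seq_len(k) - 1)) %% 3
  sel <- digits > 0
  list(members = modelIds[sel],
       classes = stats::setNames(CLASS_LEVELS[digits[sel]], modelIds[sel]))
}

#' Enumerate every pattern over a model universe
#'
#' Yields all `3^k - 1` (subset, class-assignment) pairs exactly once, in
#' ternary-code order (equivalently: subsets in lexicographic model order
#' with assignments in binary order, low before high).
#'
#' @param modelIds Distinct model identifiers (at most 12).
#' @return data.frame with columns `index` (ternary code), `size` (number
#'   of members), `members` (comma-joined ids) and `assignment`
#'   (comma-joined `id=class`).
#' @examples
#' nrow(enumeratePatterns(c("A_f", "D_f")))  # 8
#' @export
enumeratePatterns <- function(modelIds = allModelIds()) {
  if (anyDuplicated(modelIds)) {
    stop("model ids must be distinct", call. = FALSE)
  }
  k <- length(modelIds)
  if (k < 1 || k > 12) stop("need 1..12 model ids", call. = FALSE)
  describePatterns(seq_len(3^k - 1), modelIds)
}

# Pattern table rows for a set of ternary codes (same columns as
# enumeratePatterns, without materialising the full 3^k - 1 enumeration).
describePatterns <- function(idx, modelIds) {
  k <- length(modelIds)
  n <- length(idx)
  digits <- outer(idx, 3^(seq_len(k) - 1), function(i, p) (i %/% p) %% 3)
  tokensM <- matrix("", n, k)
  tokensA <- matrix("", n, k)
  for (j in seq_len(k)) {
    sel <- digits[, j] > 0
    tokensM[sel, j] <- modelIds[j]
    tokensA[sel, j] <- paste0(modelIds[j], "=", CLASS_LEVELS[digits[sel, j]])
  }
  join <- function(tok) {
    joined <- do.call(paste, c(asplit(tok, 2), sep = ","))
    gsub("^,+|,+$", "", gsub(",{2,}", ",", joined))
  }
  data.frame(index = idx, size = rowSums(digits > 0),
             members = join(tokensM), assignment = join(tokensA),
             stringsAsFactors = FALSE)
}

#' Does a prediction row match a pattern?
#'
#' Conjunctive semantics: the row matches iff every member model's
#' predicted class equals the pattern's assigned class.
#'
#' @param pattern A list with `members` and named `classes` (as returned by
#'   [patternFromIndex()] or a [plantedRule()]).
#' @param row Named character vector of predicted classes (names are model
#'   ids), e.g. one column of [predictedClasses()].
#' @return Logical scalar.
#' @export
matchPattern <- function(pattern, row) {
  if (!all(pattern$members %in% names(row))) {
    stop("row is missing predictions for: ",
         paste(setdiff(pattern$members, names(row)), collapse = ", "),
         call. = FALSE)
  }
  all(row[pattern$members] == pattern$classes[pattern$members])
}

# All ternary codes matched by each sample. A sample matches exactly the
# patterns built from subsets of the models with the sample's own predicted
# classes, i.e. 2^k codes per sample (including the empty code 0).
# Returns a (2^k x nsamples) integer matrix.
sampleMatchCodes <- function(pred, modelIds) {
  k <- length(modelIds)
  pred <- pred[modelIds, , drop = FALSE]
  digitValue <- (1L + (pred == "high")) * 3^(seq_len(k) - 1)
  subsets <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  subsets %*% digitValue
}

#' Mine complete-specificity patterns across shuffles
#'
#' Exhaustively evaluates every pattern over the model universe against
#' the test predictions of each shuffle and keeps those that (i) in every
#' shuffle where they match at least one sample, match samples of only one
#' true fruit-A class ("complete specificity"), (ii) imply the same class
#' in every shuffle where they match ("predictive in the same direction"),
#' and (iii) match in at least `minSupport` shuffles. Shuffles where a
#' pattern matches nothing neither qualify nor disqualify it.
#'
#' Per-shuffle sensitivity of a pattern is
#' `100 * matched samples of the implied class / total test samples of the
#' implied class in that shuffle` (`NA` where it matched none).
#'
#' @param tables List of [PredictionSet-class] objects, one per shuffle
#'   (typically the test subsets).
#' @param minSupport Minimum number of shuffles a pattern must match in;
#'   default 1. Must not exceed the number of shuffles.
#' @return A [PatternSet-class].
#' @export
minePatterns <- function(tables, minSupport = 1) {
  if (length(tables) < 1) stop("need at least one shuffle", call. = FALSE)
  if (minSupport > length(tables)) {
    stop("minSupport exceeds the number of shuffles", call. = FALSE)
  }
  if (minSupport < 1) stop("minSupport must be >= 1", call. = FALSE)
  mids <- modelIds(tables[[1]])
  if (length(mids) > 12) stop("too many models to enumerate", call. = FALSE)
  nsh <- length(tables)
  K <- 3^length(mids) - 1
  NL <- matrix(0L, nsh, K)
  NH <- matrix(0L, nsh, K)
  sampleIndex <- vector("list", nsh)
  trueByShuffle <- vector("list", nsh)
  totals <- data.frame(shuffle = seq_len(nsh), n_low = 0L, n_high = 0L)
  for (s in seq_len(nsh)) {
    ps <- tables[[s]]
    if (!identical(modelIds(ps), mids)) {
      stop("all shuffles must share the same model universe", call. = FALSE)
    }
    if (ncol(ps) == 0) stop("shuffle ", s, " has no samples", call. = FALSE)
    codes <- sampleMatchCodes(predictedClasses(ps), mids)
    trueA <- trueClasses(ps)
    lowCodes <- codes[, trueA == "low", drop = FALSE]
    highCodes <- codes[, trueA == "high", drop = FALSE]
    if (ncol(lowCodes)) NL[s, ] <- tabulate(lowCodes, nbins = K)
    if (ncol(highCodes)) NH[s, ] <- tabulate(highCodes, nbins = K)
    sampleIndex[[s]] <- codes
    trueByShuffle[[s]] <- trueA
    totals$n_low[s] <- sum(trueA == "low")
    totals$n_high[s] <- sum(trueA == "high")
  }
  impure <- colSums(NL > 0 & NH > 0) > 0
  evLow <- colSums(NL > 0) > 0
  evHigh <- colSums(NH > 0) > 0
  support <- colSums((NL + NH) > 0)
  keep <- which(!impure & xor(evLow, evHigh) & support >= minSupport)

  pat <- describePatterns(keep, mids)
  pat$implied_class <- ifelse(evLow[keep], "low", "high")
  pat$support <- support[keep]
  rownames(pat) <- NULL

  mL <- NL[, keep, drop = FALSE]
  mH <- NH[, keep, drop = FALSE]
  sens <- matrix(NA_real_, nsh, length(keep))
  for (s in seq_len(nsh)) {
    cnt <- ifelse(pat$implied_class == "low", mL[s, ], mH[s, ])
    tot <- ifelse(pat$implied_class == "low", totals$n_low[s],
                  totals$n_high[s])
    sens[s, ] <- ifelse(cnt > 0, 100 * cnt / tot, NA_real_)
  }
  new("PatternSet", modelIds = mids, nShuffles = as.integer(nsh),
      patterns = pat, sensitivity = sens, matchedLow = mL, matchedHigh = mH,
      classTotals = totals, sampleIndex = sampleIndex,
      trueClassByShuffle = trueByShuffle)
}

#' Sensitivity as a function of minimum shuffle support
#'
#' For each support threshold `m` from the number of shuffles down to 1,
#' restricts the mined patterns to those matching in at least `m` shuffles
#' and reports, per implied class: the number of qualifying patterns and
#' the mean and standard deviation across shuffles of the union-coverage
#' sensitivity — the percentage of that shuffle's true-class test samples
#' matched by at least one qualifying pattern. Pattern counts are
#' non-decreasing as `m` decreases.
#'
#' @param mined A [PatternSet-class] from [minePatterns()].
#' @param perPattern If `TRUE`, additionally report the mean across
#'   qualifying patterns of each pattern's own mean per-shuffle
#'   sensitivity (the alternative reading of "average sensitivity").
#' @return data.frame with one row per support level `m` and columns
#'   `min_support`, `n_patterns_low`, `n_patterns_high`,
#'   `mean_sensitivity_low`, `sd_low`, `mean_sensitivity_high`, `sd_high`
#'   (and `per_pattern_mean_low`/`_high` when `perPattern`).
#' @export
sensitivityCurve <- function(mined, perPattern = FALSE) {
  stopifnot(is(mined, "PatternSet"))
  nsh <- mined@nShuffles
  pat <- mined@patterns
  K <- 3^length(mined@modelIds) - 1
  rows <- lapply(seq(nsh, 1), function(m) {
    row <- list(min_support = m)
    for (cl in CLASS_LEVELS) {
      sel <- pat$implied_class == cl & pat$support >= m
      row[[paste0("n_patterns_", cl)]] <- sum(sel)
      if (!any(sel)) {
        cov <- rep(NA_real_, nsh)
      } else {
        mask <- logical(K + 1)          # mask[code + 1]
        mask[pat$index[sel] + 1] <- TRUE
        cov <- vapply(seq_len(nsh), function(s) {
          codes <- mined@sampleIndex[[s]]
          inClass <- mined@trueClassByShuffle[[s]] == cl
          if (!any(inClass)) return(NA_real_)
          hit <- colSums(matrix(mask[codes[, inClass, drop = FALSE] + 1],
                                nrow = nrow(codes))) > 0
          100 * mean(hit)
        }, numeric(1))
      }
      row[[paste0("mean_sensitivity_", cl)]] <- mean(cov, na.rm = FALSE)
      row[[paste0("sd_", cl)]] <- sd(cov)
      if (perPattern) {
        row[[paste0("per_pattern_mean_", cl)]] <- if (any(sel)) {
          mean(colMeans(mined@sensitivity[, sel, drop = FALSE],
                        na.rm = TRUE))
        } else NA_real_
      }
    }
    as.data.frame(row)
  })
  do.call(rbind, rows)
}

#' Boost fruit-A predictions with mined patterns
#'
#' Each sample is matched against the mined patterns (optionally restricted
#' to a minimum shuffle support). A sample matching at least one pattern
#' whose implied classes all agree is predicted that class; matching
#' patterns of both directions yields `"conflict"`; matching none yields
#' `"abstain"`.
#'
#' @param x A [PredictionSet-class] or a single named character vector of
#'   predicted classes.
#' @param mined A [PatternSet-class].
#' @param minSupport Optional support filter applied before matching.
#' @return Character vector with values in
#'   `c("low", "high", "abstain", "conflict")`, one per sample.
#' @export
boostPredictions <- function(x, mined, minSupport = NULL) {
  stopifnot(is(mined, "PatternSet"))
  pred <- if (is(x, "PredictionSet")) predictedClasses(x)
          else matrix(x[mined@modelIds], ncol = 1,
                      dimnames = list(mined@modelIds, NULL))
  if (!all(mined@modelIds %in% rownames(pred)) || anyNA(pred)) {
    stop("predictions missing for some models", call. = FALSE)
  }
  pat <- mined@patterns
  if (!is.null(minSupport)) pat <- pat[pat$support >= minSupport, ]
  K <- 3^length(mined@modelIds) - 1
  maskLow <- maskHigh <- logical(K + 1)
  maskLow[pat$index[pat$implied_class == "low"] + 1] <- TRUE
  maskHigh[pat$index[pat$implied_class == "high"] + 1] <- TRUE
  codes <- sampleMatchCodes(pred, mined@modelIds)
  anyL <- colSums(matrix(maskLow[codes + 1], nrow = nrow(codes))) > 0
  anyH <- colSums(matrix(maskHigh[codes + 1], nrow = nrow(codes))) > 0
  out <- rep("abstain", ncol(codes))
  out[anyL & !anyH] <- "low"
  out[anyH & !anyL] <- "high"
  out[anyL & anyH] <- "conflict"
  out
}

#' Pick / Do-not-Pick decision
#'
#' Resolves the boosted fruit-A class to the field decision: `Pick` when
#' the resolved class is `high` (the commercially desired,
#' azadirachtin-rich class), `Do not Pick` otherwise. When the boosted
#' result is `abstain` or `conflict` the raw single-analyte fruit-A
#' prediction is used as fallback, and conflicts are flagged.
#'
#' @param boosted Character vector from [boostPredictions()].
#' @param fallback Character vector of raw fruit-A predictions
#'   (`"low"`/`"high"`), same length.
#' @return data.frame with columns `decision` (`"Pick"`/`"Do not Pick"`),
#'   `resolved_class`, `used_fallback` and `conflict`.
#' @export
decidePick <- function(boosted, fallback) {
  if (length(boosted) != length(fallback)) {
    stop("boosted and fallback must have equal length", call. = FALSE)
  }
  if (!all(fallback %in% CLASS_LEVELS)) {
    stop("fallback predictions must be 'low' or 'high'", call. = FALSE)
  }
  usedFallback <- boosted %in% c("abstain", "conflict")
  resolved <- ifelse(usedFallback, fallback, boosted)
  data.frame(
    decision = ifelse(resolved == "high", "Pick", "Do not Pick"),
    resolved_class = resolved,
    used_fallback = usedFallback,
    conflict = boosted == "conflict",
    stringsAsFactors = FALSE
  )
}
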