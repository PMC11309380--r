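#' F1 score from precision and recall
#'
#' Harmonic mean `2 P R / (P + R)`. When both precision and recall are 0
#' the harmonic mean is undefined; 0 is returned with a message.
#'
#' @param precision,recall Proportions in `[0, 1]`.
#' @return F1 in `[0, 1]`; always between `min(P, R)` and `max(P, R)`.
#' @examples
#' f1Score(0.83, 0.93)  # 0.877... -> prints as 0.88
#' @export
f1Score <- function(precision, recall) {
  stopifnot(is.numeric(precision), is.numeric(recall))
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1)) {
    stop("precision and recall must lie in [0, 1]", call. = FALSE)
  }
  denom <- precision + recall
  out <- ifelse(denom == 0, 0, 2 * precision * recall / denom)
  if (any(denom == 0)) message("f1Score: P = R = 0; F1 reported as 0")
  out
}

#' 2x2 confusion counts
#'
#' Tabulates predictions against truths with respect to a designated
#' positive class.
#'
#' @param preds,truths Character vectors of `"low"`/`"high"`, equal length.
#' @param positive The class counted as positive.
#' @return Named list of class `"ConfusionCounts"` with integer fields
#'   `tp`, `fp`, `tn`, `fn` and the `positive` class.
#' @export
confusionCounts <- function(preds, truths, positive = "high") {
  if (length(preds) != length(truths)) {
    stop("preds and truths must have equal length", call. = FALSE)
  }
  if (!all(c(preds, truths) %in% CLASS_LEVELS)) {
    stop("classes must be 'low' or 'high'", call. = FALSE)
  }
  positive <- match.arg(positive, CLASS_LEVELS)
  p <- preds == positive
  t <- truths == positive
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t),
                 positive = positive),
            class = "ConfusionCounts")
}

#' Per-class sensitivity and specificity (percent)
#'
#' `sensitivity = 100 tp / (tp + fn)`; `specificity = 100 tn / (tn + fp)`.
#' When a denominator is zero the corresponding metric is `NA` (undefined),
#' never 0.
#'
#' @param counts A [confusionCounts()] object.
#' @return Named numeric vector `c(sensitivity, specificity)` in percent.
#' @export
classSensitivitySpecificity <- function(counts) {
  stopifnot(inherits(counts, "ConfusionCounts"))
  sens <- if (counts$tp + counts$fn > 0) {
    100 * counts$tp / (counts$tp + counts$fn)
  } else NA_real_
  spec <- if (counts$tn + counts$fp > 0) {
    100 * counts$tn / (counts$tn + counts$fp)
  } else NA_real_
  c(sensitivity = sens, specificity = spec)
}

#' Cross-validation error across shuffles
#'
#' Arithmetic mean of per-shuffle error proportions, with the companion
#' sample standard deviation.
#'
#' @param per_shuffle_errors Numeric vector of proportions in `[0, 1]`.
#' @return Named numeric vector `c(mean, sd)`; `sd` is `NA` for a single
#'   shuffle.
#' @export
cvError <- function(per_shuffle_errors) {
  if (length(per_shuffle_errors) == 0) {
    stop("need at least one per-shuffle error", call. = FALSE)
  }
  if (any(per_shuffle_errors < 0 | per_shuffle_errors > 1)) {
    stop("errors must lie in [0, 1]", call. = FALSE)
  }
  c(mean = mean(per_shuffle_errors), sd = sd(per_shuffle_errors))
}

#' Full metrics report for one set of predictions
#'
#' Per-class precision, recall and F1 (class `l` = low, `h` = high), their
#' macro average over the two classes (`a`), and per-class sensitivity and
#' specificity in percent. Sensitivity of a class equals the recall with
#' that class taken as positive.
#'
#' @param preds,truths Character vectors of `"low"`/`"high"`.
#' @return Nested list: `$precision`, `$recall`, `$f1` each with fields
#'   `a`, `l`, `h`; `$sensitivity` and `$specificity` with fields `l`, `h`
#'   (percent); `$n` scored samples.
#' @export
metricsReport <- function(preds, truths) {
  per <- lapply(stats::setNames(CLASS_LEVELS, c("l", "h")), function(cl) {
    cc <- confusionCounts(preds, truths, positive = cl)
    prec <- if (cc$tp + cc$fp > 0) cc$tp / (cc$tp + cc$fp) else NA_real_
    rec <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_
    ss <- classSensitivitySpecificity(cc)
    list(precision = prec, recall = rec,
         f1 = if (!is.na(prec) && !is.na(rec)) f1Score(prec, rec)
              else NA_real_,
         sensitivity = ss[["sensitivity"]],
         specificity = ss[["specificity"]])
  })
  macro <- function(field) {
    mean(c(per$l[[field]], per$h[[field]]))
  }
  list(
    precision = list(a = macro("precision"), l = per$l$precision,
                     h = per$h$precision),
    recall = list(a = macro("recall"), l = per$l$recall, h = per$h$recall),
    f1 = list(a = macro("f1"), l = per$l$f1, h = per$h$f1),
    sensitivity = list(l = per$l$sensitivity, h = per$h$sensitivity),
    specificity = list(l = per$l$specificity, h = per$h$specificity),
    n = length(preds)
  )
}
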