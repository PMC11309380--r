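#' @import methods
#' @importFrom stats setNames qbeta pnorm rbinom runif sd rnorm cor quantile
#' @importFrom utils read.csv write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' PredictionSet: surrogate model predictions with ground truth
#'
#' An S4 container extending
#' [SummarizedExperiment::SummarizedExperiment] holding the predicted
#' classes of the ten metabolite models. Rows are models, columns are
#' samples; the single assay `"predicted"` is a character matrix with
#' values `"low"`/`"high"`. True per-metabolite classes live in `colData`
#' as columns `true_A` ... `true_S`, optionally alongside the simulated
#' concentrations (`conc_A` ...).
#'
#' @seealso [simulatePredictions()], [minePatterns()]
#' @aliases PredictionSet
#' @export
setClass("PredictionSet",
         contains = "SummarizedExperiment")

setValidity("PredictionSet", function(object) {
  msgs <- character()
  if (!"predicted" %in% SummarizedExperiment::assayNames(object)) {
    msgs <- c(msgs, "assay 'predicted' is required")
  } else {
    p <- SummarizedExperiment::assay(object, "predicted")
    if (!all(p %in% CLASS_LEVELS)) {
      msgs <- c(msgs, "predicted classes must be 'low' or 'high'")
    }
  }
  if (is.null(rownames(object)) || !all(rownames(object) %in% allModelIds())) {
    msgs <- c(msgs, "rownames must be model ids from allModelIds()")
  }
  if (anyDuplicated(rownames(object))) {
    msgs <- c(msgs, "duplicate model ids")
  }
  if (!"true_A" %in% colnames(SummarizedExperiment::colData(object))) {
    msgs <- c(msgs, "colData must contain true_A")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PredictionSet
#'
#' @param predicted Character matrix of `"low"`/`"high"`, models in rows
#'   (rownames are model ids), samples in columns.
#' @param trueClasses data.frame of true classes, one row per sample,
#'   columns named by metabolite (`A` ... `S`), values `"low"`/`"high"`.
#' @param concentrations Optional numeric data.frame of concentrations with
#'   the same row order and metabolite columns.
#' @param sampleIds Optional sample identifiers; defaults to the column
#'   names of `predicted` or `sample_1 ...`.
#' @return A [PredictionSet-class] object.
#' @export
PredictionSet <- function(predicted, trueClasses, concentrations = NULL,
                          sampleIds = NULL) {
  predicted <- as.matrix(predicted)
  n <- ncol(predicted)
  if (is.null(sampleIds)) {
    sampleIds <- colnames(predicted)
    if (is.null(sampleIds)) sampleIds <- paste0("sample_", seq_len(n))
  }
  colnames(predicted) <- sampleIds
  cd <- S4Vectors::DataFrame(row.names = sampleIds)
  for (m in intersect(metaboliteNames(), colnames(trueClasses))) {
    cd[[paste0("true_", m)]] <- as.character(trueClasses[[m]])
  }
  if (!is.null(concentrations)) {
    for (m in intersect(metaboliteNames(), colnames(concentrations))) {
      cd[[paste0("conc_", m)]] <- as.numeric(concentrations[[m]])
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(predicted = predicted), colData = cd)
  new("PredictionSet", se)
}

#' @describeIn PredictionSet-class Model identifiers (row names).
#' @param x,object A `PredictionSet`.
#' @export
setGeneric("modelIds", function(x) standardGeneric("modelIds"))

#' @rdname PredictionSet
#' @export
setMethod("modelIds", "PredictionSet", function(x) rownames(x))

#' Predicted class matrix of a PredictionSet
#'
#' @param x A [PredictionSet-class].
#' @return Character matrix, models in rows, samples in columns.
#' @export
setGeneric("predictedClasses", function(x) standardGeneric("predictedClasses"))

#' @rdname predictedClasses
#' @export
setMethod("predictedClasses", "PredictionSet", function(x) {
  SummarizedExperiment::assay(x, "predicted")
})

#' True classes stored in a PredictionSet
#'
#' @param x A [PredictionSet-class].
#' @param metabolite Metabolite letter; default `"A"` (fruit azadirachtin,
#'   the prediction target).
#' @return Character vector of `"low"`/`"high"`, one per sample.
#' @export
setGeneric("trueClasses", function(x, metabolite = "A") {
  standardGeneric("trueClasses")
})

#' @rdname trueClasses
#' @export
setMethod("trueClasses", "PredictionSet", function(x, metabolite = "A") {
  col <- paste0("true_", match.arg(metabolite, metaboliteNames()))
  cd <- SummarizedExperiment::colData(x)
  if (!col %in% colnames(cd)) stop("no ", col, " in colData", call. = FALSE)
  as.character(cd[[col]])
})

setMethod("show", "PredictionSet", function(object) {
  cat("PredictionSet:", nrow(object), "models x", ncol(object), "samples\n")
  tc <- table(trueClasses(object))
  cat("  true fruit-A classes:",
      paste(names(tc), tc, sep = "=", collapse = ", "), "\n")
  cat("  models:", paste(rownames(object), collapse = " "), "\n")
})

#' PatternSet: mined complete-specificity patterns
#'
#' Result of [minePatterns()]. Holds the qualifying patterns (a pattern is
#' a subset of models with one assigned class per member), the fruit-A
#' class each implies, per-shuffle match counts and sensitivities, and the
#' per-sample match index needed to evaluate union coverage and boosted
#' predictions on the selection shuffles.
#'
#' @slot modelIds character, the model universe used for enumeration.
#' @slot nShuffles integer, number of dataset shuffles mined.
#' @slot patterns data.frame with columns `index`, `size`, `members`,
#'   `assignment`, `implied_class`, `support`.
#' @slot sensitivity numeric matrix (shuffle x pattern) of per-shuffle
#'   sensitivities in percent; `NA` where the pattern matched no sample.
#' @slot matchedLow,matchedHigh integer matrices (shuffle x pattern) of
#'   matched test samples by true fruit-A class.
#' @slot classTotals data.frame per shuffle: `n_low`, `n_high` test samples.
#' @slot sampleIndex list (one per shuffle) of integer matrices giving, for
#'   each test sample, the ternary codes of every pattern it matches.
#' @slot trueClassByShuffle list of character vectors of true fruit-A
#'   classes per shuffle.
#' @export
setClass("PatternSet",
         representation(modelIds = "character",
                        nShuffles = "integer",
                        patterns = "data.frame",
                        sensitivity = "matrix",
                        matchedLow = "matrix",
                        matchedHigh = "matrix",
                        classTotals = "data.frame",
                        sampleIndex = "list",
                        trueClassByShuffle = "list"))

setValidity("PatternSet", function(object) {
  p <- object@patterns
  need <- c("index", "size", "members", "assignment", "implied_class",
            "support")
  if (!all(need %in% colnames(p))) return("missing pattern columns")
  if (nrow(p) && !all(p$implied_class %in% CLASS_LEVELS)) {
    return("implied_class must be low/high")
  }
  if (ncol(object@sensitivity) != nrow(p)) {
    return("sensitivity matrix does not match pattern table")
  }
  TRUE
})

#' @describeIn PatternSet-class Number of mined patterns.
#' @param x,object A `PatternSet`.
#' @export
setGeneric("nPatterns", function(x) standardGeneric("nPatterns"))

#' @rdname PatternSet-class
#' @export
setMethod("nPatterns", "PatternSet", function(x) nrow(x@patterns))

#' @describeIn PatternSet-class Pattern table (one row per mined pattern).
#' @export
setGeneric("patterns", function(x) standardGeneric("patterns"))

#' @rdname PatternSet-class
#' @export
setMethod("patterns", "PatternSet", function(x) x@patterns)

#' @describeIn PatternSet-class Shuffle support of each mined pattern.
#' @export
setGeneric("patternSupport", function(x) standardGeneric("patternSupport"))

#' @rdname PatternSet-class
#' @export
setMethod("patternSupport", "PatternSet", function(x) {
  stats::setNames(x@patterns$support, x@patterns$assignment)
})

setMethod("show", "PatternSet", function(object) {
  p <- object@patterns
  cat("PatternSet:", nrow(p), "complete-specificity patterns over",
      length(object@modelIds), "models,", object@nShuffles, "shuffles\n")
  if (nrow(p)) {
    cat("  implied low :", sum(p$implied_class == "low"),
        " implied high:", sum(p$implied_class == "high"), "\n")
    cat("  support range:", min(p$support), "-", max(p$support), "\n")
  }
})

#' MultiAnalyteResult: one full cross-validation experiment
#'
#' Returned by [runExperiment()]. Bundles the per-shuffle single-analyte
#' and boosted metrics, the mined [PatternSet-class], the
#' sensitivity-versus-support curve and the aggregate (mean ± SD) report.
#'
#' @slot config list, the experiment configuration used.
#' @slot seed integer seed of record.
#' @slot shuffles list of per-shuffle results (metrics + decisions).
#' @slot mined A [PatternSet-class].
#' @slot curve data.frame, the sensitivity-versus-support curve.
#' @slot aggregate list of aggregate statistics (means and sample SDs
#'   across shuffles).
#' @export
setClass("MultiAnalyteResult",
         representation(config = "list", seed = "integer",
                        shuffles = "list", mined = "PatternSet",
                        curve = "data.frame", aggregate = "list"))

#' @describeIn MultiAnalyteResult-class Aggregate report (means and SDs).
#' @param x,object A `MultiAnalyteResult`.
#' @export
setGeneric("aggregateReport", function(x) standardGeneric("aggregateReport"))

#' @rdname MultiAnalyteResult-class
#' @export
setMethod("aggregateReport", "MultiAnalyteResult", function(x) x@aggregate)

#' @describeIn MultiAnalyteResult-class Mined pattern set.
#' @export
setGeneric("minedPatterns", function(x) standardGeneric("minedPatterns"))

#' @rdname MultiAnalyteResult-class
#' @export
setMethod("minedPatterns", "MultiAnalyteResult", function(x) x@mined)

#' @describeIn MultiAnalyteResult-class Sensitivity-versus-support curve.
#' @export
setGeneric("sensitivitySupportCurve", function(x) {
  standardGeneric("sensitivitySupportCurve")
})

#' @rdname MultiAnalyteResult-class
#' @export
setMethod("sensitivitySupportCurve", "MultiAnalyteResult",
          function(x) x@curve)

setMethod("show", "MultiAnalyteResult", function(object) {
  ag <- object@aggregate
  cat("MultiAnalyteResult:", length(object@shuffles), "shuffles, n =",
      object@config$n_samples, "\n")
  fmt <- function(v) sprintf("%.2f +/- %.2f", v["mean"], v["sd"])
  cat("  single-analyte sensitivity low :",
      fmt(ag$single$sensitivity_low), "\n")
  cat("  single-analyte sensitivity high:",
      fmt(ag$single$sensitivity_high), "\n")
  cat("  boosted sensitivity low :", fmt(ag$boosted$sensitivity_low), "\n")
  cat("  boosted sensitivity high:", fmt(ag$boosted$sensitivity_high), "\n")
  cat("  boosted specificity (pooled) low/high:",
      sprintf("%.2f / %.2f", ag$boosted$specificity_low_pooled,
              ag$boosted$specificity_high_pooled), "\n")
  cat("  mined patterns:", nPatterns(object@mined), "\n")
})
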