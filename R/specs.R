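#' Canonical model and metabolite identifiers
#'
#' The five neem secondary metabolites (A = azadirachtin, D =
#' deacetyl-salannin, E = nimbolide, N = nimbin, S = salannin) and the ten
#' per-image classifiers built from them: one fruit model and one leaf model
#' per metabolite.
#'
#' @return `metaboliteNames()` returns the five metabolite letters;
#'   `allModelIds()` returns the ten model identifiers, fruit models first,
#'   in metabolite order (`A_f`, `D_f`, ..., `S_l`).
#' @export
metaboliteNames <- function() c("A", "D", "E", "N", "S")

#' @rdname metaboliteNames
#' @export
allModelIds <- function() {
  c(paste0(metaboliteNames(), "_f"), paste0(metaboliteNames(), "_l"))
}

CLASS_LEVELS <- c("low", "high")

#' Metabolite concentration specification
#'
#' Describes the marginal distribution of one metabolite's concentration:
#' its observed range and mean. Concentrations are simulated from a beta
#' distribution rescaled to `[min_conc, max_conc]` whose mean equals
#' `mean_conc`, so values respect the bounds without truncation.
#'
#' @param name Metabolite letter, one of `"A"`, `"D"`, `"E"`, `"N"`, `"S"`.
#' @param min_conc,max_conc Lower and upper bounds of the concentration
#'   (arbitrary concentration units).
#' @param mean_conc Target mean, strictly between the bounds.
#' @param shape_sum Total `alpha + beta` of the underlying beta
#'   distribution; larger values concentrate mass around the mean.
#' @return A list of class `"MetaboliteSpec"`.
#' @examples
#' metaboliteSpec("A", 0.181, 1.003, 0.563)
#' @export
metaboliteSpec <- function(name, min_conc, max_conc, mean_conc, shape_sum = 4) {
  name <- match.arg(name, metaboliteNames())
  stopifnot(is.numeric(min_conc), is.numeric(max_conc), is.numeric(mean_conc))
  if (!(min_conc < mean_conc && mean_conc < max_conc)) {
    stop("invalid MetaboliteSpec for ", name,
         ": need min_conc < mean_conc < max_conc", call. = FALSE)
  }
  if (shape_sum <= 0) stop("shape_sum must be positive", call. = FALSE)
  structure(
    list(name = name, min_conc = min_conc, max_conc = max_conc,
         mean_conc = mean_conc, shape_sum = shape_sum),
    class = "MetaboliteSpec"
  )
}

#' Default metabolite specifications
#'
#' The observed concentration ranges and means of the five metabolites in
#' the neem fruit reference dataset (n = 1045 trees).
#'
#' @return Named list of [metaboliteSpec()] objects in metabolite order.
#' @export
defaultMetaboliteSpecs <- function() {
  list(
    A = metaboliteSpec("A", 0.181, 1.003, 0.563),
    D = metaboliteSpec("D", 0.007, 0.691, 0.112),
    E = metaboliteSpec("E", 0.004, 0.252, 0.045),
    N = metaboliteSpec("N", 0.009, 0.501, 0.163),
    S = metaboliteSpec("S", 0.056, 1.420, 0.511)
  )
}

#' Surrogate predictor specification
#'
#' Per-class sensitivities of one surrogate binary classifier: the
#' probability that a truly `low` sample is predicted `low` (`sens_low`)
#' and that a truly `high` sample is predicted `high` (`sens_high`).
#' Conditional on the true class, predictors are independent across models
#' unless a planted rule applies.
#'
#' @param model_id One of the ten identifiers from [allModelIds()].
#' @param sens_low,sens_high Probabilities in `[0, 1]`.
#' @return A list of class `"PredictorSpec"`.
#' @export
predictorSpec <- function(model_id, sens_low, sens_high) {
  if (!model_id %in% allModelIds()) {
    stop("unknown model_id: ", model_id, call. = FALSE)
  }
  stopifnot(is.numeric(sens_low), is.numeric(sens_high))
  if (sens_low < 0 || sens_low > 1 || sens_high < 0 || sens_high > 1) {
    stop("sensitivities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(model_id = model_id, sens_low = sens_low, sens_high = sens_high),
    class = "PredictorSpec"
  )
}

#' Default surrogate predictor specifications
#'
#' Per-class sensitivities placed at the test-set operating points of the
#' trained detectors: the fruit azadirachtin model at 0.8352 / 0.8235
#' (low / high), the remaining fruit models near their per-class test
#' recalls, and the leaf models substantially weaker, reproducing the
#' fruit-versus-leaf performance gap.
#'
#' @return Named list of [predictorSpec()] objects, one per model id.
#' @export
defaultPredictorSpecs <- function() {
  tab <- list(
    A_f = c(0.8352, 0.8235),
    D_f = c(0.95, 0.94),
    E_f = c(0.88, 0.92),
    N_f = c(0.87, 0.86),
    S_f = c(0.98, 0.96),
    A_l = c(0.65, 0.80),
    D_l = c(0.77, 0.73),
    E_l = c(0.60, 0.73),
    N_l = c(0.72, 0.79),
    S_l = c(0.73, 0.73)
  )
  out <- lapply(names(tab), function(m) {
    predictorSpec(m, tab[[m]][1], tab[[m]][2])
  })
  names(out) <- names(tab)
  out
}

#' Planted deterministic rule
#'
#' A ground-truth association planted into simulated predictions so that
#' pattern recovery can be tested. A rule states that a conjunction of
#' predicted classes over a subset of models (the antecedent) is diagnostic
#' of one true fruit-azadirachtin class.
#'
#' Exactly `round(coverage * n)` of the samples whose true fruit-A class
#' equals `implied_class` receive the full antecedent; chance matches on the
#' remaining implied-class samples are always broken (one randomly chosen
#' member flipped), so `coverage` is the exact antecedent prevalence within
#' the implied class. Chance matches on opposite-class samples are broken
#' the same way with probability `penetrance`; at `penetrance = 1` the
#' antecedent is therefore perfectly specific for `implied_class` by
#' construction.
#'
#' @param members Character vector of model ids (subset of [allModelIds()]).
#' @param classes Character vector, one of `"low"`/`"high"` per member.
#' @param implied_class True fruit-A class the antecedent implies.
#' @param coverage Exact fraction of implied-class samples that carry the
#'   antecedent. Default 1.
#' @param penetrance Probability that a chance antecedent match on an
#'   opposite-class sample is broken. Default 1 (perfect specificity).
#' @return A list of class `"PlantedRule"`.
#' @examples
#' plantedRule(c("D_f", "S_f"), c("high", "high"), "high")
#' @export
plantedRule <- function(members, classes, implied_class,
                        coverage = 1, penetrance = 1) {
  if (length(members) < 1 || anyDuplicated(members) ||
      !all(members %in% allModelIds())) {
    stop("members must be a non-empty set of distinct model ids",
         call. = FALSE)
  }
  if (length(classes) != length(members) || !all(classes %in% CLASS_LEVELS)) {
    stop("classes must give 'low'/'high' for each member", call. = FALSE)
  }
  implied_class <- match.arg(implied_class, CLASS_LEVELS)
  if (penetrance <= 0 || penetrance > 1) {
    stop("penetrance must lie in (0, 1]", call. = FALSE)
  }
  if (coverage <= 0 || coverage > 1) {
    stop("coverage must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(members = as.character(members),
         classes = stats::setNames(as.character(classes), members),
         implied_class = implied_class,
         coverage = coverage, penetrance = penetrance),
    class = "PlantedRule"
  )
}

# Rules implying different classes must disagree on at least one shared
# member, otherwise one sample could satisfy both antecedents and the
# implied truths would contradict.
validateRules <- function(rules) {
  if (length(rules) < 2) return(invisible(TRUE))
  for (i in seq_along(rules)) {
    for (j in seq_len(i - 1L)) {
      a <- rules[[i]]; b <- rules[[j]]
      if (a$implied_class == b$implied_class) next
      shared <- intersect(a$members, b$members)
      if (length(shared) == 0 ||
          all(a$classes[shared] == b$classes[shared])) {
        stop("planted rules imply different classes but their antecedents ",
             "can co-occur on one sample", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
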