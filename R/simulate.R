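#' Simulate metabolite concentration records
#'
#' Draws per-sample concentrations for the five metabolites. Each marginal
#' is a beta distribution rescaled to the metabolite's `[min, max]` range
#' with shape parameters solved so its mean equals the target mean, so
#' simulated values respect the printed bounds without clipping. Dependence
#' between metabolites is induced by a Gaussian copula: latent multivariate
#' normals with the requested correlation matrix are mapped through their
#' normal CDF to uniforms, then through each metabolite's beta quantile
#' function. The `correlation` argument is therefore the latent (copula)
#' correlation; the induced Spearman correlation is `(6/pi) * asin(rho/2)`,
#' slightly attenuated.
#'
#' @param n Number of samples (trees); `n >= 1`.
#' @param specs Named list of [metaboliteSpec()]s; default
#'   [defaultMetaboliteSpecs()].
#' @param correlation Either a single off-diagonal value (exchangeable
#'   correlation) or a full symmetric positive semi-definite matrix with
#'   unit diagonal, dimension = number of metabolites. Default 0.3
#'   exchangeable: the metabolites co-occur in the same biosynthetic
#'   pathway and are positively associated, but no field estimate of the
#'   strength exists.
#' @param seed Integer seed; fixing it fixes the output exactly.
#' @return data.frame with columns `sample_id` and one numeric column per
#'   metabolite.
#' @examples
#' conc <- simulateConcentrations(100, seed = 1)
#' range(conc$A)  # within [0.181, 1.003]
#' @export
simulateConcentrations <- function(n, specs = defaultMetaboliteSpecs(),
                                   correlation = 0.3, seed = 1) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  k <- length(specs)
  R <- expandCorrelation(correlation, k)
  checkCorrelation(R)
  withr::with_seed(as.integer(seed), {
    Z <- matrix(rnorm(n * k), n, k) %*% corFactor(R)
    U <- pnorm(Z)
    out <- data.frame(sample_id = sprintf("s%05d", seq_len(n)))
    for (j in seq_len(k)) {
      sp <- specs[[j]]
      mu01 <- (sp$mean_conc - sp$min_conc) / (sp$max_conc - sp$min_conc)
      a <- sp$shape_sum * mu01
      b <- sp$shape_sum * (1 - mu01)
      out[[sp$name]] <- sp$min_conc +
        (sp$max_conc - sp$min_conc) * qbeta(U[, j], a, b)
    }
    out
  })
}

expandCorrelation <- function(correlation, k) {
  if (is.matrix(correlation)) return(correlation)
  if (length(correlation) != 1) {
    stop("correlation must be a scalar or a matrix", call. = FALSE)
  }
  R <- matrix(correlation, k, k)
  diag(R) <- 1
  R
}

checkCorrelation <- function(R) {
  if (!isSymmetric(unname(R), tol = 1e-8)) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(R) - 1) > 1e-8)) {
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("correlation matrix is not positive semi-definite", call. = FALSE)
  }
  invisible(TRUE)
}

# Square root of a PSD correlation matrix via its eigendecomposition
# (chol() would reject semi-definite inputs).
corFactor <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(vals)))
}

#' Simulate surrogate model predictions
#'
#' Stands in for the trained per-image detectors: each of the ten models
#' predicts its own metabolite's true class correctly with the per-class
#' sensitivity from its [predictorSpec()], independently across models
#' given the truth. Planted rules (see [plantedRule()]) then overwrite
#' member predictions so that their antecedent occurs on exactly the
#' configured `coverage` fraction of implied-class samples; at
#' `penetrance = 1` it occurs only on samples of the implied class.
#'
#' @param concentrations data.frame from [simulateConcentrations()] (only
#'   `sample_id` is required).
#' @param labels data.frame from [assignClasses()] covering every sample
#'   and metabolite.
#' @param predictors Named list of [predictorSpec()]s; default
#'   [defaultPredictorSpecs()].
#' @param rules List of [plantedRule()]s (possibly empty).
#' @param seed Integer seed.
#' @return A [PredictionSet-class].
#' @export
simulatePredictions <- function(concentrations, labels,
                                predictors = defaultPredictorSpecs(),
                                rules = list(), seed = 1) {
  ids <- allModelIds()
  got <- vapply(predictors, function(p) p$model_id, character(1))
  if (!all(got %in% ids)) {
    stop("unknown model_id in predictors: ",
         paste(setdiff(got, ids), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(got)) stop("duplicate predictor model_id", call. = FALSE)
  missing_ids <- setdiff(ids, got)
  if (length(missing_ids)) {
    stop("predictors missing for: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  m <- match(concentrations$sample_id, labels$sample_id)
  if (anyNA(m)) stop("labels do not cover all samples", call. = FALSE)
  labels <- labels[m, , drop = FALSE]
  if (!all(metaboliteNames() %in% colnames(labels))) {
    stop("labels must contain a class column per metabolite", call. = FALSE)
  }
  validateRules(rules)
  n <- nrow(concentrations)
  names(predictors) <- got

  withr::with_seed(as.integer(seed), {
    pred <- matrix(NA_character_, length(ids), n,
                   dimnames = list(ids, concentrations$sample_id))
    for (mid in ids) {
      sp <- predictors[[mid]]
      metab <- sub("_[fl]$", "", mid)
      truth <- as.character(labels[[metab]])
      sens <- ifelse(truth == "low", sp$sens_low, sp$sens_high)
      correct <- runif(n) < sens
      other <- ifelse(truth == "low", "high", "low")
      pred[mid, ] <- ifelse(correct, truth, other)
    }
    trueA <- as.character(labels$A)
    for (rule in rules) {
      # plant the antecedent on exactly round(coverage * n) implied-class
      # samples, so coverage is the exact antecedent prevalence in that class
      eligible <- which(trueA == rule$implied_class)
      nCover <- round(rule$coverage * length(eligible))
      planted <- eligible[sample.int(length(eligible), nCover)]
      for (mm in rule$members) pred[mm, planted] <- rule$classes[[mm]]
      # break chance matches outside the covered set: always on uncovered
      # implied-class samples (keeping coverage exact), with probability
      # penetrance on opposite-class samples
      rest <- setdiff(seq_len(n), planted)
      matches <- rest[colSums(
        pred[rule$members, rest, drop = FALSE] != rule$classes) == 0]
      sameClass <- trueA[matches] == rule$implied_class
      broken <- matches[sameClass |
                          runif(length(matches)) < rule$penetrance]
      for (cls in unique(trueA[broken])) {
        idx <- broken[trueA[broken] == cls]
        free <- flipCandidates(rule, rules, cls)
        picks <- free[sample.int(length(free), length(idx),
                                 replace = TRUE)]
        pred[cbind(match(picks, rownames(pred)), idx)] <-
          ifelse(rule$classes[picks] == "low", "high", "low")
      }
    }
    PredictionSet(pred,
                  trueClasses = labels[, metaboliteNames(), drop = FALSE],
                  concentrations =
                    concentrations[, intersect(metaboliteNames(),
                                               colnames(concentrations)),
                                   drop = FALSE])
  })
}

# Antecedent members eligible to flip when breaking a chance match on a
# sample of class `sample_true_class`: exclude members that another rule
# (one implying that class) plants with the same assignment -- the flip
# must not erode that rule.
flipCandidates <- function(rule, rules, sample_true_class) {
  protected <- character(0)
  for (other in rules) {
    if (identical(other, rule)) next
    if (other$implied_class != sample_true_class) next
    shared <- intersect(other$members, rule$members)
    protected <- c(protected,
                   shared[other$classes[shared] == rule$classes[shared]])
  }
  free <- setdiff(rule$members, protected)
  if (length(free)) free else rule$members
}
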