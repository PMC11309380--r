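#' Read and write pipeline tables
#'
#' All tables are comma-separated UTF-8 CSV with a header row. Writers and
#' readers round-trip without loss.
#'
#' `writeConcentrations()`/`readConcentrations()` handle the per-sample
#' concentration table (`sample_id,A,D,E,N,S`);
#' `writeLabels()`/`readLabels()` the class table with the same layout;
#' `writeSplits()`/`readSplits()` the split assignments
#' (`sample_id,shuffle_id,subset`).
#'
#' @param x data.frame to write.
#' @param path File path.
#' @return Readers return a data.frame; writers return `path` invisibly.
#' @name tableIO
NULL

#' @rdname tableIO
#' @export
writeConcentrations <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tableIO
#' @export
readConcentrations <- function(path) {
  readCsvChecked(path, c("sample_id", metaboliteNames()))
}

#' @rdname tableIO
#' @export
writeLabels <- writeConcentrations

#' @rdname tableIO
#' @export
readLabels <- function(path) {
  readCsvChecked(path, c("sample_id", metaboliteNames()))
}

#' @rdname tableIO
#' @export
writeSplits <- writeConcentrations

#' @rdname tableIO
#' @export
readSplits <- function(path) {
  readCsvChecked(path, c("sample_id", "shuffle_id", "subset"))
}

readCsvChecked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, colnames(x))
  if (length(missing)) {
    stop("malformed CSV ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x
}

#' Serialize a PredictionSet to a flat CSV
#'
#' Wide layout, one row per sample: `sample_id`, `true_<metabolite>` for
#' each metabolite present, optional `conc_<metabolite>` columns, and
#' `pred_<model>` for each of the ten models. An optional `shuffle_id`
#' column allows several shuffles in one file.
#'
#' @param ps A [PredictionSet-class] or a named list of them (one per
#'   shuffle; names or positions become `shuffle_id`).
#' @param path CSV path.
#' @return `readPredictionSet()` returns a [PredictionSet-class] (or a list
#'   of them when the file has a `shuffle_id` column).
#' @export
writePredictionSet <- function(ps, path) {
  one <- function(p, sh = NULL) {
    cd <- as.data.frame(SummarizedExperiment::colData(p))
    out <- data.frame(sample_id = colnames(p))
    if (!is.null(sh)) out$shuffle_id <- sh
    for (cc in grep("^(true|conc)_", colnames(cd), value = TRUE)) {
      out[[cc]] <- cd[[cc]]
    }
    pm <- t(predictedClasses(p))
    colnames(pm) <- paste0("pred_", colnames(pm))
    cbind(out, as.data.frame(pm))
  }
  df <- if (is(ps, "PredictionSet")) one(ps) else {
    do.call(rbind, lapply(seq_along(ps), function(i) one(ps[[i]], i)))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePredictionSet
#' @export
readPredictionSet <- function(path) {
  df <- readCsvChecked(path, c("sample_id", "true_A"))
  build <- function(d) {
    predCols <- grep("^pred_", colnames(d), value = TRUE)
    if (!length(predCols)) {
      stop("malformed CSV ", path, ": no pred_* columns", call. = FALSE)
    }
    pred <- t(as.matrix(d[, predCols, drop = FALSE]))
    rownames(pred) <- sub("^pred_", "", predCols)
    colnames(pred) <- d$sample_id
    trueCols <- grep("^true_", colnames(d), value = TRUE)
    tc <- d[, trueCols, drop = FALSE]
    colnames(tc) <- sub("^true_", "", trueCols)
    concCols <- grep("^conc_", colnames(d), value = TRUE)
    conc <- if (length(concCols)) {
      cn <- d[, concCols, drop = FALSE]
      colnames(cn) <- sub("^conc_", "", concCols)
      cn
    } else NULL
    PredictionSet(pred, tc, conc, sampleIds = d$sample_id)
  }
  if ("shuffle_id" %in% colnames(df)) {
    lapply(split(df, df$shuffle_id), build)
  } else {
    build(df)
  }
}

#' Serialize mined patterns as JSON
#'
#' Writes the pattern table with per-shuffle support and sensitivity — the
#' machine-readable analogue of a supplementary pattern listing.
#'
#' @param mined A [PatternSet-class].
#' @param path JSON path.
#' @return `readPatternsJSON()` returns a list with `model_ids`,
#'   `n_shuffles` and a data.frame `patterns` (columns as in
#'   [patterns()] plus `shuffle_sensitivity`, a list column).
#' @export
writePatternsJSON <- function(mined, path) {
  pat <- mined@patterns
  pat$shuffle_sensitivity <- lapply(seq_len(nrow(pat)), function(i) {
    unname(mined@sensitivity[, i])
  })
  obj <- list(model_ids = mined@modelIds,
              n_shuffles = mined@nShuffles,
              class_totals = mined@classTotals,
              patterns = pat)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writePatternsJSON
#' @export
readPatternsJSON <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$patterns <- as.data.frame(obj$patterns)
  obj
}

#' Reconstruct a matcher from serialized patterns
#'
#' Rebuilds a minimal [PatternSet-class] from [readPatternsJSON()] output,
#' sufficient for [boostPredictions()] and [decidePick()] (per-sample match
#' indices of the selection shuffles are not restored).
#'
#' @param obj List from [readPatternsJSON()].
#' @return A [PatternSet-class].
#' @export
patternSetFromJSON <- function(obj) {
  pat <- obj$patterns
  sens <- if (nrow(pat)) {
    do.call(cbind, lapply(pat$shuffle_sensitivity, function(v) {
      as.numeric(unlist(v))
    }))
  } else matrix(numeric(0), as.integer(obj$n_shuffles), 0)
  pat$shuffle_sensitivity <- NULL
  new("PatternSet", modelIds = as.character(obj$model_ids),
      nShuffles = as.integer(obj$n_shuffles), patterns = pat,
      sensitivity = sens,
      matchedLow = matrix(0L, as.integer(obj$n_shuffles), nrow(pat)),
      matchedHigh = matrix(0L, as.integer(obj$n_shuffles), nrow(pat)),
      classTotals = as.data.frame(obj$class_totals),
      sampleIndex = list(), trueClassByShuffle = list())
}

#' Experiment configuration YAML
#'
#' `writeExperimentConfig()` writes a [experimentConfig()] as YAML;
#' `readExperimentConfig()` reads and validates one. Metabolite specs,
#' predictor specs and planted rules are stored under `specs`,
#' `predictors` and `rules`.
#'
#' @param config A `metaboostConfig`.
#' @param path YAML path.
#' @return `readExperimentConfig()` returns a validated
#'   [experimentConfig()].
#' @export
writeExperimentConfig <- function(config, path) {
  stopifnot(inherits(config, "metaboostConfig"))
  obj <- unclass(config)
  obj$specs <- lapply(config$specs, unclass)
  obj$predictors <- lapply(config$predictors, unclass)
  obj$rules <- lapply(config$rules, function(r) {
    list(members = r$members, classes = unname(r$classes),
         implied_class = r$implied_class, coverage = r$coverage,
         penetrance = r$penetrance)
  })
  if (is.matrix(obj$correlation)) {
    obj$correlation <- apply(obj$correlation, 1, as.numeric,
                             simplify = FALSE)
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writeExperimentConfig
#' @export
readExperimentConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("malformed YAML ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  specs <- if (!is.null(obj$specs)) {
    lapply(obj$specs, function(s) {
      metaboliteSpec(s$name, s$min_conc, s$max_conc, s$mean_conc,
                     if (is.null(s$shape_sum)) 4 else s$shape_sum)
    })
  } else defaultMetaboliteSpecs()
  predictors <- if (!is.null(obj$predictors)) {
    lapply(obj$predictors, function(p) {
      predictorSpec(p$model_id, p$sens_low, p$sens_high)
    })
  } else defaultPredictorSpecs()
  rules <- if (!is.null(obj$rules)) {
    lapply(obj$rules, function(r) {
      plantedRule(unlist(r$members), unlist(r$classes), r$implied_class,
                  coverage = if (is.null(r$coverage)) 1 else r$coverage,
                  penetrance = if (is.null(r$penetrance)) 1
                               else r$penetrance)
    })
  } else list()
  correlation <- obj$correlation
  if (is.list(correlation)) {
    correlation <- do.call(rbind, lapply(correlation, unlist))
  }
  grab <- function(field, default) {
    if (is.null(obj[[field]])) default else obj[[field]]
  }
  experimentConfig(
    n_samples = grab("n_samples", 1045),
    n_shuffles = grab("n_shuffles", 10),
    ratios = unlist(grab("ratios", c(0.8, 0.1, 0.1))),
    specs = specs,
    correlation = if (is.null(correlation)) 0.3 else correlation,
    predictors = predictors,
    rules = rules,
    min_support = grab("min_support", grab("n_shuffles", 10)),
    stratified = grab("stratified", FALSE),
    honest_eval = grab("honest_eval", FALSE)
  )
}

#' Run manifest
#'
#' Records how a set of output files was produced: configuration hash
#' (MD5 of the config YAML), seed, package version, output file list and a
#' timestamp. Re-running the same command with the same config and seed
#' reproduces the listed outputs.
#'
#' @param configPath Path to the config YAML used (may be `NA`).
#' @param seed Integer seed of record.
#' @param outputs Character vector of produced file paths.
#' @param path Where to write the manifest JSON.
#' @return The manifest list, invisibly.
#' @export
writeManifest <- function(configPath, seed, outputs, path) {
  manifest <- list(
    package = "metaboost",
    version = as.character(utils::packageVersion("metaboost")),
    seed = as.integer(seed),
    config = if (!is.na(configPath)) basename(configPath) else NA,
    config_md5 = if (!is.na(configPath) && file.exists(configPath)) {
      unname(tools::md5sum(configPath))
    } else NA,
    outputs = basename(outputs),
    output_md5 = unname(tools::md5sum(outputs[file.exists(outputs)])),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  invisible(manifest)
}

#' Flatten an aggregate report for CSV output
#'
#' One row per (framework, metric) with mean and SD, percentages on the
#' 0-100 scale rounded to two decimals.
#'
#' @param result A [MultiAnalyteResult-class].
#' @return data.frame with columns `framework`, `metric`, `mean`, `sd`.
#' @export
aggregateAsCSV <- function(result) {
  ag <- aggregateReport(result)
  rows <- list()
  for (fw in c("single", "boosted")) {
    for (metric in names(ag[[fw]])) {
      v <- ag[[fw]][[metric]]
      if (is.numeric(v) && length(v) == 2 &&
          identical(names(v), c("mean", "sd"))) {
        rows[[length(rows) + 1]] <- data.frame(
          framework = fw, metric = metric,
          mean = round(v[["mean"]], 2), sd = round(v[["sd"]], 2))
      } else if (is.numeric(v) && length(v) == 1) {
        rows[[length(rows) + 1]] <- data.frame(
          framework = fw, metric = metric, mean = round(v, 2),
          sd = NA_real_)
      }
    }
  }
  do.call(rbind, rows)
}
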