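#' Convert concentrations to binary classes by mean thresholds
#'
#' A sample is labeled `high` for a metabolite when its concentration
#' exceeds that metabolite's threshold and `low` otherwise; a concentration
#' exactly equal to the threshold is labeled `low` (the labeling rule
#' covers strictly-below and strictly-above, so the boundary needs a fixed
#' convention to stay deterministic). Thresholds default to the means from
#' [defaultMetaboliteSpecs()].
#'
#' Samples with a missing concentration for any requested metabolite are
#' excluded with a warning naming them.
#'
#' @param concentrations data.frame with `sample_id` and one numeric column
#'   per metabolite.
#' @param thresholds Named numeric vector of per-metabolite thresholds;
#'   each must lie strictly inside the observed range of its metabolite.
#' @return data.frame with `sample_id` and one class column (`"low"` /
#'   `"high"`) per metabolite.
#' @examples
#' conc <- data.frame(sample_id = "s1", A = 1.003)
#' assignClasses(conc, thresholds = c(A = 0.563))$A  # "high"
#' @export
assignClasses <- function(concentrations,
                          thresholds = vapply(defaultMetaboliteSpecs(),
                                              `[[`, numeric(1),
                                              "mean_conc")) {
  metabs <- intersect(metaboliteNames(), colnames(concentrations))
  if (!length(metabs)) stop("no metabolite columns found", call. = FALSE)
  if (!all(metabs %in% names(thresholds))) {
    stop("thresholds missing for: ",
         paste(setdiff(metabs, names(thresholds)), collapse = ", "),
         call. = FALSE)
  }
  for (m in metabs) {
    obs <- range(concentrations[[m]], na.rm = TRUE)
    if (!is.na(obs[1]) && obs[1] < obs[2] &&
        (thresholds[[m]] <= obs[1] || thresholds[[m]] >= obs[2])) {
      stop("threshold for ", m, " lies outside the observed range",
           call. = FALSE)
    }
  }
  bad <- rowSums(is.na(concentrations[, metabs, drop = FALSE])) > 0
  if (any(bad)) {
    warning("excluding ", sum(bad), " sample(s) with missing ",
            "concentrations: ",
            paste(utils::head(concentrations$sample_id[bad], 5),
                  collapse = ", "),
            if (sum(bad) > 5) ", ..." else "", call. = FALSE)
    concentrations <- concentrations[!bad, , drop = FALSE]
  }
  out <- data.frame(sample_id = concentrations$sample_id)
  for (m in metabs) {
    out[[m]] <- ifelse(concentrations[[m]] > thresholds[[m]], "high", "low")
  }
  out
}

#' Random train/validation/test splits across shuffles
#'
#' Each shuffle is an independent uniform permutation of the samples cut
#' into train/validation/test at the given ratios. Subset sizes are
#' `floor(n * ratio)` with any remainder assigned to train (the largest
#' share). Splits are simple random, not class-stratified: the reference
#' experiment shows unequal class counts across its splits, consistent with
#' unstratified sampling. Set `stratifyBy` to a class vector to stratify.
#'
#' @param samples Character vector of sample identifiers.
#' @param ratios Numeric length-3 vector `(train, validation, test)`
#'   summing to 1. Default `c(0.8, 0.1, 0.1)`.
#' @param nShuffles Number of independent shuffles; default 10.
#' @param seed Integer seed; all shuffles are drawn from one seeded stream,
#'   so shuffle `i` is reproducible given `(seed, i)`.
#' @param stratifyBy Optional character vector (same length as `samples`)
#'   of class labels; splits are then drawn within each class.
#' @return data.frame with columns `sample_id`, `shuffle_id` (1-based),
#'   `subset` (`"train"`/`"validation"`/`"test"`).
#' @examples
#' sp <- makeSplits(paste0("s", 1:10), nShuffles = 1, seed = 1)
#' table(sp$subset)  # 8 train, 1 validation, 1 test
#' @export
makeSplits <- function(samples, ratios = c(0.8, 0.1, 0.1), nShuffles = 10,
                       seed = 1, stratifyBy = NULL) {
  if (abs(sum(ratios) - 1) > 1e-8 || length(ratios) != 3 ||
      any(ratios <= 0)) {
    stop("ratios must be three positive proportions summing to 1",
         call. = FALSE)
  }
  if (nShuffles < 1) stop("nShuffles must be >= 1", call. = FALSE)
  n <- length(samples)
  sizes <- floor(n * ratios)
  sizes[1] <- sizes[1] + (n - sum(sizes))
  if (any(sizes < 1)) {
    stop("too few samples for three non-empty subsets", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    res <- lapply(seq_len(nShuffles), function(sh) {
      if (is.null(stratifyBy)) {
        perm <- sample.int(n)
        subset <- rep(c("train", "validation", "test"), sizes)
        subset <- subset[order(perm)]  # position i's subset
      } else {
        subset <- character(n)
        for (cl in unique(stratifyBy)) {
          idx <- which(stratifyBy == cl)
          perm <- sample(idx)
          sz <- floor(length(idx) * ratios)
          sz[1] <- sz[1] + (length(idx) - sum(sz))
          subset[perm] <- rep(c("train", "validation", "test"), sz)
        }
      }
      data.frame(sample_id = samples, shuffle_id = sh, subset = subset)
    })
    do.call(rbind, res)
  })
}
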