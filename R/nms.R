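#' Detection boxes
#'
#' Detections use the five-coordinate YOLO convention: normalized center
#' coordinates and side lengths in `[0, 1]`, plus a class and a confidence.
#' Represented as a data.frame with columns `class`, `x_center`,
#' `y_center`, `width`, `height` and (optionally) `confidence`.
#'
#' @param class Character or integer class per box.
#' @param x_center,y_center,width,height Normalized box geometry.
#' @param confidence Confidence in `[0, 1]`; optional.
#' @return data.frame of boxes.
#' @export
detectionBoxes <- function(class, x_center, y_center, width, height,
                           confidence = NULL) {
  geom <- cbind(x_center, y_center, width, height)
  if (any(geom < 0 | geom > 1)) {
    stop("box coordinates must be normalized to [0, 1]", call. = FALSE)
  }
  out <- data.frame(class = class, x_center = x_center,
                    y_center = y_center, width = width, height = height,
                    stringsAsFactors = FALSE)
  if (!is.null(confidence)) {
    if (any(confidence < 0 | confidence > 1)) {
      stop("confidence must lie in [0, 1]", call. = FALSE)
    }
    out$confidence <- confidence
  }
  out
}

#' Intersection-over-union of center-format boxes
#'
#' @param a One box (a one-row data.frame or list with `x_center`,
#'   `y_center`, `width`, `height`).
#' @param b A data.frame of boxes.
#' @return Numeric vector of IoU values in `[0, 1]`, one per row of `b`.
#' @export
iou <- function(a, b) {
  ax1 <- a$x_center - a$width / 2; ax2 <- a$x_center + a$width / 2
  ay1 <- a$y_center - a$height / 2; ay2 <- a$y_center + a$height / 2
  bx1 <- b$x_center - b$width / 2; bx2 <- b$x_center + b$width / 2
  by1 <- b$y_center - b$height / 2; by2 <- b$y_center + b$height / 2
  iw <- pmax(0, pmin(ax2, bx2) - pmax(ax1, bx1))
  ih <- pmax(0, pmin(ay2, by2) - pmax(ay1, by1))
  inter <- iw * ih
  union <- a$width * a$height + b$width * b$height - inter
  ifelse(union > 0, inter / union, 0)
}

#' Greedy non-max suppression
#'
#' Boxes below the confidence threshold are dropped; the survivors are
#' processed in order of decreasing confidence, each kept box suppressing
#' every remaining box of the same class whose IoU with it exceeds
#' `iouThreshold`. Output is sorted by decreasing confidence. Ties in
#' confidence are broken by input order (first wins), keeping the
#' procedure deterministic.
#'
#' @param boxes data.frame of boxes with a `confidence` column (see
#'   [detectionBoxes()]).
#' @param confThreshold Minimum confidence to keep; default 0.25, the
#'   mobile pipeline's reporting cutoff.
#' @param iouThreshold IoU above which a lower-confidence same-class box is
#'   suppressed; default 0.45, the detector family's default.
#' @return data.frame, a subset of the input rows.
#' @export
nms <- function(boxes, confThreshold = 0.25, iouThreshold = 0.45) {
  if (is.null(boxes) || nrow(boxes) == 0) return(boxes)
  stopifnot("confidence" %in% colnames(boxes))
  boxes <- boxes[boxes$confidence >= confThreshold, , drop = FALSE]
  if (nrow(boxes) == 0) return(boxes)
  ord <- order(-boxes$confidence, seq_len(nrow(boxes)))
  boxes <- boxes[ord, , drop = FALSE]
  keep <- logical(nrow(boxes))
  alive <- rep(TRUE, nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    rest <- which(alive & seq_len(nrow(boxes)) > i)
    if (!length(rest)) break
    same <- rest[boxes$class[rest] == boxes$class[i]]
    if (length(same)) {
      ov <- iou(boxes[i, ], boxes[same, , drop = FALSE])
      alive[same[ov > iouThreshold]] <- FALSE
    }
  }
  boxes[keep, , drop = FALSE]
}

#' Top-1 detection
#'
#' The highest-confidence box of a post-NMS set (the mobile pipeline keeps
#' only the top result); ties are broken by input order. `NULL` for an
#' empty set.
#'
#' @param boxes data.frame of boxes with `confidence`.
#' @return One-row data.frame or `NULL`.
#' @export
top1Box <- function(boxes) {
  if (is.null(boxes) || nrow(boxes) == 0) return(NULL)
  boxes[which.max(boxes$confidence), , drop = FALSE]
}

#' Read / write YOLO-format label files
#'
#' One box per line: `class x_center y_center width height [confidence]`,
#' whitespace-separated, coordinates normalized to `[0, 1]`.
#'
#' @param path Path to a `.txt` label file.
#' @return `readYoloLabels()`: data.frame of boxes (empty for an empty
#'   file).
#' @export
readYoloLabels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- detectionBoxes(character(0), numeric(0), numeric(0),
                          numeric(0), numeric(0), numeric(0))
  if (!length(lines)) return(empty)
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(parts)
  if (any(nf < 5 | nf > 6)) {
    stop("malformed YOLO label in ", path, " (line ",
         which(nf < 5 | nf > 6)[1], "): expected 5 or 6 fields",
         call. = FALSE)
  }
  vals <- t(vapply(parts, function(p) as.numeric(p[-1][1:5]), numeric(5)))
  detectionBoxes(vapply(parts, `[`, character(1), 1),
                 vals[, 1], vals[, 2], vals[, 3], vals[, 4],
                 confidence = if (all(nf == 6)) vals[, 5] else NULL)
}

#' @rdname readYoloLabels
#' @param boxes data.frame of boxes.
#' @export
writeYoloLabels <- function(boxes, path) {
  fields <- c("class", "x_center", "y_center", "width", "height")
  hasConf <- "confidence" %in% colnames(boxes)
  lines <- apply(boxes, 1, function(r) {
    vals <- c(r[["class"]],
              formatC(as.numeric(r[fields[-1]]), format = "f", digits = 6))
    if (hasConf) {
      vals <- c(vals, formatC(as.numeric(r[["confidence"]]),
                              format = "f", digits = 6))
    }
    paste(vals, collapse = " ")
  })
  writeLines(if (nrow(boxes)) lines else character(0), path)
  invisible(path)
}
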