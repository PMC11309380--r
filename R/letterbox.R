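#' Aspect-fit letterbox to a square canvas
#'
#' Geometric stage of the mobile detector's pre-processing: the image is
#' scaled by `s = target / max(h, w)` (aspect ratio preserved, bilinear
#' interpolation), pasted centered onto a `target x target` canvas, and the
#' remaining area is filled with a constant gray (114 on the 0-255 scale,
#' the detector family's training fill). A 640 x 640 input passes through
#' unchanged (`s = 1`, no padding).
#'
#' The subsequent tensor conversion steps (transpose, BGR to RGB, 0-255 to
#' 0-1) are applied by [toModelInput()] so that `letterbox()` itself is
#' idempotent on already-letterboxed input.
#'
#' @param image Numeric array `h x w x 3` (or `h x w`), values on the 0-255
#'   scale.
#' @param target Side length of the square output; default 640.
#' @param fill Padding gray value; default 114.
#' @return List with `image` (the `target x target x 3` canvas, 0-255),
#'   `scale` (`s`), `pad` (`c(top, left)` offsets in pixels) and
#'   `original` (`c(h, w)`).
#' @export
letterbox <- function(image, target = 640, fill = 114) {
  if (length(dim(image)) == 2) {
    image <- array(rep(image, 3), c(dim(image), 3))
  }
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3 || d[1] < 1 || d[2] < 1) {
    stop("image must be a non-empty h x w x 3 array", call. = FALSE)
  }
  h <- d[1]; w <- d[2]
  s <- target / max(h, w)
  nh <- max(1L, as.integer(round(h * s)))
  nw <- max(1L, as.integer(round(w * s)))
  resized <- if (nh == h && nw == w) image else {
    out <- array(0, c(nh, nw, 3))
    for (ch in 1:3) out[, , ch] <- resizeBilinear(image[, , ch], nh, nw)
    out
  }
  canvas <- array(fill, c(target, target, 3))
  top <- (target - nh) %/% 2
  left <- (target - nw) %/% 2
  canvas[top + seq_len(nh), left + seq_len(nw), ] <- resized
  list(image = canvas, scale = s, pad = c(top = top, left = left),
       original = c(h = h, w = w))
}

# Bilinear interpolation with pixel centers at (i - 0.5), matching the
# usual image-resize convention (edge pixels clamped).
resizeBilinear <- function(m, nh, nw) {
  h <- nrow(m); w <- ncol(m)
  y <- (seq_len(nh) - 0.5) * h / nh + 0.5
  x <- (seq_len(nw) - 0.5) * w / nw + 0.5
  y0 <- pmin(pmax(floor(y), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(x), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(y - y0, 0), 1)
  fx <- pmin(pmax(x - x0, 0), 1)
  top <- m[y0, x0, drop = FALSE] * (1 - fx)[col(matrix(0, nh, nw))] +
    m[y0, x1, drop = FALSE] * fx[col(matrix(0, nh, nw))]
  bot <- m[y1, x0, drop = FALSE] * (1 - fx)[col(matrix(0, nh, nw))] +
    m[y1, x1, drop = FALSE] * fx[col(matrix(0, nh, nw))]
  top * (1 - fy) + bot * fy
}

#' Convert a letterboxed canvas to model input layout
#'
#' Applies the final tensor steps of the mobile pipeline: transpose the
#' spatial axes, reverse the channel order (BGR to RGB), and rescale values
#' from 0-255 to 0-1.
#'
#' @param image `h x w x 3` numeric array on the 0-255 scale (e.g. the
#'   `image` element of [letterbox()]).
#' @param channelOrder Channel order of the input; `"BGR"` (default, the
#'   camera byte order) is reversed to RGB, `"RGB"` is kept.
#' @return `w x h x 3` numeric array with values in `[0, 1]`, RGB order.
#' @export
toModelInput <- function(image, channelOrder = c("BGR", "RGB")) {
  channelOrder <- match.arg(channelOrder)
  d <- dim(image)
  stopifnot(length(d) == 3, d[3] == 3)
  out <- aperm(image, c(2, 1, 3))
  if (channelOrder == "BGR") out <- out[, , 3:1, drop = FALSE]
  out / 255
}

#' Map letterboxed coordinates back to the original image
#'
#' Inverts the geometry recorded by [letterbox()]: subtract the padding
#' offsets and divide by the scale.
#'
#' @param xy Numeric matrix (or length-2 vector) of `(x, y)` pixel
#'   coordinates on the letterboxed canvas.
#' @param meta The list returned by [letterbox()].
#' @return Matrix of coordinates in the original image's pixel frame.
#' @export
unletterbox <- function(xy, meta) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  cbind(x = (xy[, 1] - meta$pad[["left"]]) / meta$scale,
        y = (xy[, 2] - meta$pad[["top"]]) / meta$scale)
}

#' Read a PNG image as a 0-255 array
#'
#' @param path Path to a PNG file.
#' @return Numeric `h x w x 3` array on the 0-255 scale (grayscale
#'   replicated, alpha dropped).
#' @export
readImagePNG <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] == 4) a <- a[, , 1:3, drop = FALSE]
  a * 255
}

#' Write a 0-255 array as PNG
#'
#' @param image Numeric `h x w x 3` array, 0-255 scale.
#' @param path Output path.
#' @export
writeImagePNG <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}
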