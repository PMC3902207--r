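#' RGB image container
#'
#' A thin S3 wrapper around a `height x width x 3` numeric array. The
#' `stage` attribute records whether the pixel values are raw intensities
#' or the zero-mean whitened values produced by [preprocess_image()].
#'
#' @param pixels Numeric array `height x width x 3`, or a matrix (replicated
#'   over the three channels).
#' @param stage `"raw"` or `"preprocessed"`.
#' @return An `image_rgb` object.
#' @export
image_rgb <- function(pixels, stage = c("raw", "preprocessed")) {
  stage <- match.arg(stage)
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be a height x width x 3 array (RGB)")
  if (any(dim(pixels)[1:2] == 0L)) stop("degenerate (zero-area) image")
  if (!all(is.finite(pixels))) stop("image contains non-finite values")
  structure(pixels, class = "image_rgb", stage = stage)
}

#' @export
print.image_rgb <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_rgb %dx%d, %s, range [%.3g, %.3g]>\n",
              d[1], d[2], attr(x, "stage"), min(x), max(x)))
  invisible(x)
}

#' Read an RGB image from a PNG or JPEG file
#'
#' @param path File path; format selected by extension.
#' @return A raw [image_rgb()].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", ext)
  )
  if (is.matrix(px)) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  image_rgb(px, "raw")
}

# Area-averaging resize of one channel: each output pixel averages the
# source interval it covers, which anti-aliases strong downscales.
resize_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  w <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1L
    j1 <- min(ceiling(hi), n_in)
    for (j in j0:j1) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) w[i, j] <- ov
    }
    w[i, ] <- w[i, ] / sum(w[i, ])
  }
  w
}

#' Resize an RGB image
#'
#' Area-averaging (box) interpolation; downscaling is anti-aliased by
#' construction since every source pixel contributes to exactly the output
#' pixels it overlaps.
#'
#' @param image An [image_rgb()].
#' @param target Output size `c(height, width)`.
#' @return An `image_rgb` of the target size, same stage as the input.
#' @export
resize_image <- function(image, target) {
  stopifnot(length(target) == 2L, all(target >= 1))
  d <- dim(image)
  if (all(d[1:2] == target)) return(image)
  wr <- resize_weights(d[1], target[1])
  wc <- resize_weights(d[2], target[2])
  out <- array(0, c(target, 3L))
  for (ch in 1:3) out[, , ch] <- wr %*% image[, , ch] %*% t(wc)
  image_rgb(out, attr(image, "stage"))
}
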