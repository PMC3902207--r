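#' Build a smoothed ZCA whitening kernel from training images
#'
#' Estimates the pixel covariance on `patch_extent` x `patch_extent`
#' patches (all channels pooled), regularizes its eigenvalues and forms
#' the zero-phase whitening transform `U D U'` with
#' `D = diag(1 / sqrt(lambda_i + zca_reg))`. The center row of the
#' transform, reshaped to the patch extent, is returned as a convolution
#' kernel; applied convolutionally it approximates whitening the whole
#' image and has the familiar positive-center / negative-surround shape
#' on natural-like inputs.
#'
#' @param training_images List of [image_rgb()] objects (or a single one).
#' @param patch_extent Patch side length in pixels (default 12, the
#'   receptive-field size of the feature stages).
#' @param zca_reg Eigenvalue regularizer added before the inverse square
#'   root (default 0.1).
#' @param max_patches Cap on the number of patches used for the covariance
#'   estimate.
#' @return A `patch_extent` x `patch_extent` numeric matrix with class
#'   `zca_kernel`.
#' @export
build_zca_kernel <- function(training_images, patch_extent = 12L,
                             zca_reg = 0.1, max_patches = 20000L) {
  if (inherits(training_images, "image_rgb"))
    training_images <- list(training_images)
  stopifnot_scalar(zca_reg, "zca_reg")
  if (zca_reg <= 0) stop("`zca_reg` must be > 0")
  d <- as.integer(patch_extent)
  pd <- d * d
  patches <- list()
  for (img in training_images) {
    dm <- dim(img)
    if (dm[1] < d || dm[2] < d) next
    for (ch in 1:3) {
      m <- img[, , ch]
      m <- m - mean(m)
      nr <- dm[1] - d + 1L
      nc <- dm[2] - d + 1L
      rows <- seq(1L, nr, by = max(1L, d %/% 2L))
      cols <- seq(1L, nc, by = max(1L, d %/% 2L))
      for (r in rows) for (cc in cols)
        patches[[length(patches) + 1L]] <-
          as.numeric(m[r:(r + d - 1L), cc:(cc + d - 1L)])
    }
  }
  if (length(patches) < pd)
    stop("not enough patches (", length(patches),
         ") to estimate a ", pd, "-dimensional covariance")
  if (length(patches) > max_patches)
    patches <- patches[seq(1L, length(patches),
                           length.out = max_patches)]
  x <- do.call(rbind, patches)
  cv <- crossprod(sweep(x, 2L, colMeans(x))) / (nrow(x) - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  if (any(!is.finite(eg$values)) || any(eg$values < -1e-8 * max(eg$values)))
    stop("ill-conditioned patch covariance (negative eigenvalues)")
  dvals <- 1 / sqrt(pmax(eg$values, 0) + zca_reg)
  wm <- eg$vectors %*% (dvals * t(eg$vectors))
  center <- (d %/% 2L) * d + (d %/% 2L) + 1L  # column-major center pixel
  kern <- matrix(wm[center, ], d, d)
  structure(kern, class = c("zca_kernel", "matrix"),
            zca_reg = zca_reg)
}

# Convolve each channel of an (H, W, 3) array with a single-channel
# kernel, same padding, stride 1.
apply_kernel <- function(px, kern) {
  d <- dim(px)
  kd <- dim(kern)
  w <- array(kern, c(kd[1], kd[2], 1L, 1L))
  out <- array(0, d)
  for (ch in 1:3) {
    padded <- pad_same(array(px[, , ch], c(d[1], d[2], 1L)),
                       kd[1], kd[2], 1L)
    out[, , ch] <- cpp_conv_valid(padded, w, 0, 1L)[, , 1L]
  }
  out
}

#' Preprocess an image for the feature stages
#'
#' Resizes to the target extent, subtracts the per-channel mean, and
#' applies smoothed ZCA whitening as a convolutional filter. The whitening
#' kernel is built from the image itself unless one is supplied (a kernel
#' trained on a larger corpus is preferable for ensembles).
#'
#' @param image A raw [image_rgb()].
#' @param target `c(height, width)` of the output (default `c(300, 400)`).
#' @param zca_reg Whitening regularizer (default 0.1).
#' @param kernel Optional precomputed [build_zca_kernel()] result.
#' @param patch_extent Patch size used when building the kernel internally.
#' @return A preprocessed `image_rgb`: target size, per-channel means
#'   within 1e-6 of zero, whitened.
#' @export
preprocess_image <- function(image, target = c(300L, 400L), zca_reg = 0.1,
                             kernel = NULL, patch_extent = 12L) {
  if (!inherits(image, "image_rgb")) stop("`image` must be an image_rgb")
  stopifnot_scalar(zca_reg, "zca_reg")
  if (zca_reg <= 0) stop("`zca_reg` must be > 0")
  img <- resize_image(image, target)
  px <- unclass(img)
  attributes(px) <- list(dim = dim(px))
  for (ch in 1:3) px[, , ch] <- px[, , ch] - mean(px[, , ch])
  if (max(abs(px)) < 1e-12)  # constant image: nothing left to whiten
    return(image_rgb(px, "preprocessed"))
  if (is.null(kernel))
    kernel <- build_zca_kernel(list(image_rgb(px, "preprocessed")),
                               patch_extent = patch_extent,
                               zca_reg = zca_reg)
  px <- apply_kernel(px, kernel)
  # border effects of the zero-padded filter can shift the mean slightly;
  # re-center so downstream stages can rely on exact zero channel means
  for (ch in 1:3) px[, , ch] <- px[, , ch] - mean(px[, , ch])
  image_rgb(px, "preprocessed")
}
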