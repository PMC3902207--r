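#' Activation block container
#'
#' A `X x Y x K` nonnegative array of feature activations with a stage
#' tag: `"h"` (post-sigmoid), `"htilde"` (mean-subtracted and rectified)
#' or `"g"` (normalized to unit per-position sum; inactive positions all
#' zero).
#'
#' @param values Numeric 3-d array.
#' @param stage Stage tag.
#' @return An `activation_block`.
#' @export
activation_block <- function(values, stage = c("h", "htilde", "g")) {
  stage <- match.arg(stage)
  if (length(dim(values)) != 3L) stop("`values` must be a 3-d array")
  structure(values, class = "activation_block", stage = stage)
}

#' @export
print.activation_block <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<activation_block %dx%dx%d, stage %s>\n",
              d[1], d[2], d[3], attr(x, "stage")))
  invisible(x)
}

# The three-lobe monophasic Gaussian-derivative profile:
#   g_{2s}(y) * (-5 g_s(x+s) + 10.1 g_s(x) - 5 g_s(x-s))
gabor_profile <- function(x, y, sigma) {
  stats::dnorm(y, sd = 2 * sigma) *
    (-5 * stats::dnorm(x + sigma, sd = sigma) +
     10.1 * stats::dnorm(x, sd = sigma) -
     5 * stats::dnorm(x - sigma, sd = sigma))
}

#' Build the Gaussian-derivative (Gabor-like) filter bank
#'
#' Oriented difference-of-offset-Gaussian receptive fields at
#' `n_orientations` orientations in equal angular steps, applied per RGB
#' channel and duplicated with negated sign as opponent (on/off) channels.
#' With the defaults this yields the 48-channel bank
#' (8 orientations x 3 colors x 2 signs). `color = FALSE` spreads each
#' filter equally over the three channels (luminance filters), giving
#' `2 * n_orientations` channels — the desk-scale recipe configuration.
#'
#' @param sigma Gaussian scale in pixels (default 1.5; the cross profile
#'   uses `2 * sigma`).
#' @param n_orientations Number of orientations (default 8, steps of
#'   180 / n degrees).
#' @param extent Filter side length in pixels (default 12).
#' @param color Per-RGB-channel filters (default) or luminance filters.
#' @param stride Forward stride (default 2).
#' @param gain Sigmoid gain applied to the linear drive (default 1).
#' @return A `filter_bank` of kind `"gabor"` with zero biases.
#' @export
build_gabor_bank <- function(sigma = 1.5, n_orientations = 8L, extent = 12L,
                             color = TRUE, stride = 2L, gain = 1) {
  if (sigma <= 0) stop("`sigma` must be > 0")
  extent <- as.integer(extent)
  coords <- seq_len(extent) - (extent + 1) / 2
  xs <- matrix(rep(coords, each = extent), extent)   # column offset
  ys <- matrix(rep(coords, extent), extent)          # row offset
  angles <- (seq_len(n_orientations) - 1L) * pi / n_orientations
  n_col <- if (color) 3L else 1L
  K <- n_orientations * n_col * 2L
  W <- array(0, c(extent, extent, 3L, K))
  meta <- data.frame(orientation = numeric(K), channel = integer(K),
                     sign = integer(K), opponent = integer(K))
  k <- 0L
  for (i in seq_len(n_orientations)) {
    xr <- xs * cos(angles[i]) + ys * sin(angles[i])
    yr <- -xs * sin(angles[i]) + ys * cos(angles[i])
    prof <- gabor_profile(xr, yr, sigma)
    for (ch in seq_len(n_col)) {
      for (s in c(1, -1)) {
        k <- k + 1L
        if (color) W[, , ch, k] <- s * prof
        else for (cc in 1:3) W[, , cc, k] <- s * prof / 3
        meta$orientation[k] <- angles[i]
        meta$channel[k] <- ch
        meta$sign[k] <- s
        meta$opponent[k] <- k + s  # partner channel index
      }
    }
  }
  structure(list(W = W, b = rep(0, K), What = NULL, bhat = NULL,
                 stride = as.integer(stride), kind = "gabor",
                 sigma = sigma, gain = gain, meta = meta),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  d <- dim(x$W)
  cat(sprintf("<filter_bank %s: %d channels, %dx%d filters, stride %d>\n",
              x$kind, d[4], d[1], d[2], x$stride))
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Compute feedforward activations
#'
#' Strided convolution of a preprocessed image with the filter bank,
#' summed over input channels, plus bias, through the logistic sigmoid.
#' `padding = "same"` (scene runs) keeps the output grid at
#' `ceiling(image / stride)`; `"valid"` (autoencoder training) uses only
#' full filter placements.
#'
#' @param image A preprocessed [image_rgb()] (or bare 3-d array).
#' @param bank A `filter_bank`.
#' @param padding `"same"` or `"valid"`.
#' @return An [activation_block()] at stage `"h"`.
#' @export
forward_activations <- function(image, bank, padding = c("same", "valid")) {
  padding <- match.arg(padding)
  px <- unclass(image)
  attributes(px) <- list(dim = dim(px))
  d <- dim(px)
  fd <- dim(bank$W)
  if (padding == "valid" && (d[1] < fd[1] || d[2] < fd[2]))
    stop("image smaller than one filter placement")
  if (padding == "same") px <- pad_same(px, fd[1], fd[2], bank$stride)
  z <- cpp_conv_valid(px, bank$W, bank$b, bank$stride)
  gain <- if (is.null(bank$gain)) 1 else bank$gain
  activation_block(sigmoid(gain * z), "h")
}

#' Regularize activations into oscillator drive levels
#'
#' At each grid position: subtract the position's mean activation over
#' features, half-wave rectify (inactivating roughly half of the
#' neurons), then divide by the per-position sum of the rectified values.
#' Positions whose rectified sum is zero get all-zero activations and are
#' flagged inactive; they take no part in the phase coupling.
#'
#' @param h An [activation_block()] at stage `"h"` (or any nonnegative
#'   block).
#' @return An [activation_block()] at stage `"g"` with a logical
#'   `inactive` attribute (`X x Y`).
#' @export
regularize_activations <- function(h) {
  v <- unclass(h)
  attributes(v) <- list(dim = dim(v))
  if (any(v < 0)) stop("`h` must be nonnegative")
  d <- dim(v)
  mu <- array(rep(rowMeans(matrix(v, d[1] * d[2], d[3])), d[3]), d)
  ht <- pmax(0, v - mu)
  s <- array(rep(rowSums(matrix(ht, d[1] * d[2], d[3])), d[3]), d)
  g <- ifelse(s > 0, ht / s, 0)
  dim(g) <- d
  out <- activation_block(g, "g")
  attr(out, "inactive") <- matrix(s[, , 1L] == 0, d[1], d[2])
  out
}

#' Hard-sparseness kurtosis of activation levels
#'
#' Excess kurtosis of a zero-centered distribution,
#' `<h^4> / <h^2>^2 - 3`, with no mean subtraction: the activation code is
#' nonnegative, so sparseness means mass piled at exactly zero. Averages
#' run over all positions and samples; features with zero second moment
#' are reported as `NA`.
#'
#' @param h An [activation_block()] or a list of blocks (samples).
#' @return List with `per_feature` kurtosis values and their `median`
#'   (over features with defined kurtosis).
#' @export
activation_kurtosis <- function(h) {
  blocks <- if (inherits(h, "activation_block")) list(h) else h
  K <- dim(blocks[[1L]])[3]
  m2 <- numeric(K)
  m4 <- numeric(K)
  n <- 0
  for (b in blocks) {
    v <- matrix(unclass(b), ncol = K)
    m2 <- m2 + colSums(v^2)
    m4 <- m4 + colSums(v^4)
    n <- n + nrow(v)
  }
  if (n < 2L) stop("need >= 2 samples per feature")
  m2 <- m2 / n
  m4 <- m4 / n
  kurt <- ifelse(m2 > 0, m4 / m2^2 - 3, NA_real_)
  list(per_feature = kurt, median = stats::median(kurt, na.rm = TRUE))
}
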