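#' Shifted Pearson cross-correlation tensor of activations
#'
#' For every ordered feature pair `(k, m)` and spatial offset
#' `(dx, dy)` with `|dx|, |dy| <= max_offset` (neuron-grid units),
#' computes the Pearson correlation between feature `k` at a position and
#' feature `m` at the offset position, pooling paired values across all
#' valid positions and all sample blocks. Zero-variance features give
#' undefined correlations, stored as `NA` and masked out.
#'
#' @param samples An [activation_block()] or a list of them (identical
#'   dimensions).
#' @param max_offset Maximum offset in grid units (default 18, three
#'   receptive-field radii at stride 2).
#' @return A `correlation_tensor`: list with `rho` (`K x K x D x D`,
#'   `D = 2 * max_offset + 1`), `offsets` (the offset values), `n`
#'   (`D x D` pair counts), and a logical `sig` mask (initially all
#'   defined entries).
#' @export
correlation_tensor <- function(samples, max_offset = 18L) {
  blocks <- if (inherits(samples, "activation_block")) list(samples)
            else samples
  M <- as.integer(max_offset)
  d <- dim(blocks[[1L]])
  K <- d[3]
  if (d[1] <= M || d[2] <= M)
    stop("`max_offset` must be smaller than the grid extent")
  D <- 2L * M + 1L
  offs <- -M:M
  rho <- array(NA_real_, c(K, K, D, D))
  n <- matrix(0L, D, D)
  for (ix in seq_len(D)) {
    dx <- offs[ix]
    for (iy in seq_len(D)) {
      dy <- offs[iy]
      xs <- ys <- NULL
      for (b in blocks) {
        rs <- max(1L, 1L - dy):min(d[1], d[1] - dy)
        cs <- max(1L, 1L - dx):min(d[2], d[2] - dx)
        v <- unclass(b)
        x <- matrix(v[rs, cs, , drop = FALSE], ncol = K)
        y <- matrix(v[rs + dy, cs + dx, , drop = FALSE], ncol = K)
        xs <- rbind(xs, x)
        ys <- rbind(ys, y)
      }
      if (nrow(xs) < 2L) stop("need >= 2 paired samples per offset")
      rho[, , ix, iy] <- suppressWarnings(cor(xs, ys))
      n[ix, iy] <- nrow(xs)
    }
  }
  structure(list(rho = rho, offsets = offs, n = n,
                 sig = !is.na(rho), max_offset = M),
            class = "correlation_tensor")
}

#' @export
print.correlation_tensor <- function(x, ...) {
  K <- dim(x$rho)[1]
  cat(sprintf(
    "<correlation_tensor %d features, offsets +/-%d, %d significant>\n",
    K, x$max_offset, sum(x$sig)))
  invisible(x)
}

#' Mask a correlation tensor by false-discovery rate
#'
#' Two-sided p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`, then the
#' Benjamini-Hochberg-Yekutieli step-up procedure under arbitrary
#' dependence (correction factor `c(m) = sum(1/i)`). Entries that do not
#' survive are masked and treated as zero by the connection sampler.
#'
#' @param ct A [correlation_tensor()].
#' @param q Target false-discovery rate (default 0.05).
#' @return The tensor with its `sig` mask updated.
#' @export
fdr_significance_mask <- function(ct, q = 0.05) {
  stopifnot(inherits(ct, "correlation_tensor"))
  if (any(ct$n < 4L)) stop("need n >= 4 samples for the t approximation")
  D <- length(ct$offsets)
  K <- dim(ct$rho)[1]
  nn <- array(rep(ct$n, each = K * K), dim(ct$rho))
  r <- pmin(1 - 1e-15, pmax(-1 + 1e-15, ct$rho))
  tt <- r * sqrt((nn - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tt), df = nn - 2)
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  cm <- sum(1 / seq_len(m))
  o <- order(pv)
  thresh <- q * seq_len(m) / (m * cm)
  passed <- pv[o] <= thresh
  keep <- logical(m)
  if (any(passed)) {
    kstar <- max(which(passed))
    keep[o[seq_len(kstar)]] <- TRUE
  }
  sig <- array(FALSE, dim(ct$rho))
  sig[ok] <- keep
  ct$sig <- sig
  ct
}

#' Radial anisotropy profile of a correlation tensor
#'
#' Bins offsets into integer-radius rings
#' `r - 1/2 <= sqrt(dx^2 + dy^2) < r + 1/2`. For each feature pair the
#' mean and standard deviation of `|rho|` over the ring measure how
#' directional the correlation structure is; the anisotropy at radius `r`
#' is the coefficient of variation averaged over feature pairs.
#'
#' @param ct A [correlation_tensor()].
#' @return Data frame with columns `r`, `n_offsets`, `mean_abs`
#'   (mean `|rho|` over ring and pairs), `sd_dir` (ring standard
#'   deviation averaged over pairs) and `anisotropy`.
#' @export
anisotropy_profile <- function(ct) {
  stopifnot(inherits(ct, "correlation_tensor"))
  offs <- ct$offsets
  D <- length(offs)
  K <- dim(ct$rho)[1]
  dist <- sqrt(outer(offs^2, offs^2, `+`))
  out <- data.frame(r = 0:ct$max_offset)
  out$n_offsets <- NA_integer_
  out$mean_abs <- NA_real_
  out$sd_dir <- NA_real_
  out$anisotropy <- NA_real_
  flat <- matrix(abs(ct$rho), K * K, D * D)
  for (i in seq_len(nrow(out))) {
    r <- out$r[i]
    ring <- which(dist >= r - 0.5 & dist < r + 0.5)
    out$n_offsets[i] <- length(ring)
    vals <- flat[, ring, drop = FALSE]
    mu <- rowMeans(vals, na.rm = TRUE)
    out$mean_abs[i] <- mean(vals, na.rm = TRUE)
    if (length(ring) > 1L) {
      sdv <- apply(vals, 1L, sd, na.rm = TRUE)
      out$sd_dir[i] <- mean(sdv, na.rm = TRUE)
      cv <- ifelse(mu > 0, sdv / mu, NA_real_)
      out$anisotropy[i] <- mean(cv, na.rm = TRUE)
    }
  }
  out
}
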