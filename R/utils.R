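# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Wrap angles to [0, 2*pi).
wrap_phase <- function(x) x %% (2 * pi)

# Signed wrapped difference in (-pi, pi].
wrap_diff <- function(x) {
  d <- (x + pi) %% (2 * pi) - pi
  d[d == -pi] <- pi
  d
}

# Zero-pad a (H, W, C) array so that a valid convolution with an
# (fh, fw) filter at the given stride yields ceiling(H / stride) x
# ceiling(W / stride) outputs ("same" padding).
pad_same <- function(x, fh, fw, stride) {
  d <- dim(x)
  oh <- ceiling(d[1] / stride)
  ow <- ceiling(d[2] / stride)
  need_h <- (oh - 1L) * stride + fh
  need_w <- (ow - 1L) * stride + fw
  pt <- (need_h - d[1]) %/% 2L
  pl <- (need_w - d[2]) %/% 2L
  out <- array(0, c(need_h, need_w, d[3]))
  out[pt + seq_len(d[1]), pl + seq_len(d[2]), ] <- x
  out
}

# Separable Gaussian smoothing of a matrix, zero-padded borders.
gauss_smooth <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  sm_cols <- apply(m, 2L, function(col) {
    as.numeric(stats::filter(c(rep(0, half), col, rep(0, half)), k,
                             sides = 2L))[half + seq_along(col)]
  })
  t(apply(sm_cols, 1L, function(row) {
    as.numeric(stats::filter(c(rep(0, half), row, rep(0, half)), k,
                             sides = 2L))[half + seq_along(row)]
  }))
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
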