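#' Activation-weighted circular mean phase map
#'
#' `phi_avg[x,y] = Arg(sum_k g * exp(1i * phi))`. Positions with zero
#' resultant (no active features, or exactly cancelling phasors) are
#' flagged invalid. The resultant modulus is kept as a per-position
#' weight for downstream boundary statistics.
#'
#' @param phi Phase array `X x Y x K`.
#' @param g Matching [activation_block()] at stage `"g"`.
#' @return A `phase_map`: list with `phi_avg`, `valid`, `weight`.
#' @export
mean_phase_map <- function(phi, g) {
  stopifnot(identical(dim(phi), dim(g)))
  d <- dim(phi)
  gz <- matrix(unclass(g), d[1] * d[2], d[3])
  pz <- matrix(phi, d[1] * d[2], d[3])
  z <- rowSums(gz * exp(1i * pz))
  mod <- Mod(z)
  valid <- mod > 1e-12
  phi_avg <- matrix(wrap_phase(Arg(z)), d[1], d[2])
  phi_avg[!valid] <- NA_real_
  structure(list(phi_avg = phi_avg,
                 valid = matrix(valid, d[1], d[2]),
                 weight = matrix(mod, d[1], d[2])),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map %dx%d, %d invalid positions>\n",
              nrow(x$phi_avg), ncol(x$phi_avg), sum(!x$valid)))
  invisible(x)
}

#' Phase synchrony of a neuron population
#'
#' Activation-weighted mean resultant length
#' `p = |sum_M g * exp(1i * phi)| / sum_M g`, in `[0, 1]`.
#'
#' @param phi Phase array `X x Y x K`.
#' @param g Matching activations.
#' @param members Logical array selecting the population (a logical
#'   matrix selects all features at those positions; `NULL` selects
#'   everything), or an integer vector of flat indices into the array.
#' @return Synchrony in `[0, 1]`.
#' @export
population_synchrony <- function(phi, g, members = NULL) {
  gv <- unclass(g)
  if (is.null(members)) {
    idx <- seq_along(gv)
  } else if (is.matrix(members) && is.logical(members)) {
    idx <- which(array(rep(members, dim(phi)[3]), dim(phi)))
  } else if (is.logical(members)) {
    idx <- which(members)
  } else {
    idx <- as.integer(members)
  }
  wsum <- sum(gv[idx])
  if (wsum <= 0) stop("zero total activation in the population")
  Mod(sum(gv[idx] * exp(1i * phi[idx]))) / wsum
}

disc_kernel <- function(r) {
  half <- ceiling(r) - 1L
  off <- -half:half
  k <- outer(off^2, off^2, `+`) < r^2
  storage.mode(k) <- "double"
  k
}

conv2_same <- function(m, kern) {
  d <- dim(m)
  w <- array(kern, c(dim(kern), 1L, 1L))
  padded <- pad_same(array(m, c(d, 1L)), dim(kern)[1], dim(kern)[2], 1L)
  cpp_conv_valid(padded, w, 0, 1L)[, , 1L]
}

#' Mean local phase synchrony over discs
#'
#' Evaluates [population_synchrony()] over the disc
#' `(x - x0)^2 + (y - y0)^2 < r^2` (strict; all features) centered at
#' every grid position, discs clipped at the borders, and averages over
#' all positions with nonzero activation in the disc.
#'
#' @param phi Phase array `X x Y x K`.
#' @param g Matching activations.
#' @param r Disc radius in grid units (>= 1).
#' @return List with `mean`, the per-position `map`, and `r`.
#' @export
local_synchrony <- function(phi, g, r) {
  stopifnot(r >= 1)
  d <- dim(phi)
  gv <- unclass(g)
  attributes(gv) <- list(dim = d)
  kern <- disc_kernel(r)
  zre <- matrix(0, d[1], d[2])
  zim <- matrix(0, d[1], d[2])
  den <- matrix(0, d[1], d[2])
  gk <- matrix(gv, d[1] * d[2], d[3])
  pk <- matrix(phi, d[1] * d[2], d[3])
  zre[] <- rowSums(gk * cos(pk))
  zim[] <- rowSums(gk * sin(pk))
  den[] <- rowSums(gk)
  num <- sqrt(conv2_same(zre, kern)^2 + conv2_same(zim, kern)^2)
  dsum <- conv2_same(den, kern)
  ok <- dsum > 1e-12
  p <- matrix(NA_real_, d[1], d[2])
  p[ok] <- num[ok] / dsum[ok]
  list(mean = mean(p[ok]), map = p, r = r)
}

dilate_diamond <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  out[-1L, ] <- out[-1L, ] | m[-nr, ]
  out[-nr, ] <- out[-nr, ] | m[-1L, ]
  out[, -1L] <- out[, -1L] | m[, -nc]
  out[, -nc] <- out[, -nc] | m[, -1L]
  out
}

#' Grow a segment's evaluation neighborhood
#'
#' Repeats a diamond-shaped (4-neighborhood) dilation of the segment
#' mask, clipped to the grid, until the neighborhood holds at least
#' twice the segment's neurons. The surround is `R = N \ Q`.
#'
#' @param Q A [segment_mask()].
#' @return A [segment_mask()] `N` containing `Q`.
#' @export
grow_neighborhood <- function(Q) {
  m <- Q$mask
  if (!any(m)) stop("empty segment")
  target <- 2L * Q$area
  if (length(m) < target)
    stop("grid too small to double the segment area")
  while (sum(m) < target) {
    grown <- dilate_diamond(m)
    if (identical(grown, m))
      stop("grid too small to double the segment area")
    m <- grown
  }
  segment_mask(m, paste0(Q$label, "_neighborhood"))
}

sample_pool <- function(pool, size) {
  if (length(pool) >= size) sample(pool, size)
  else sample(pool, size, replace = TRUE)
}

#' Segmentation index of a labeled segment
#'
#' Compares phase synchrony inside the segment `Q` to synchrony in its
#' doubled diamond-grown neighborhood `N`: draws `n_subsets` random
#' subsets of `subset_size` neuron indices (all features at member
#' positions) from each and returns
#' `kappa = mean(p_Q_j) - mean(p_N_l)`, bounded in `[-1, 1]`.
#'
#' @param phi Phase array `X x Y x K`.
#' @param g Matching activations.
#' @param Q A [segment_mask()] on the same grid.
#' @param seed Subset sampling seed.
#' @param n_subsets,subset_size Subset scheme (defaults 100 x 1000);
#'   drawn without replacement when the pool suffices, else with.
#' @return `kappa`, with the subset synchrony vectors attached as
#'   attributes `p_Q` and `p_N`.
#' @export
segmentation_index <- function(phi, g, Q, seed = 1L, n_subsets = 100L,
                               subset_size = 1000L) {
  d <- dim(phi)
  stopifnot(identical(dim(Q$mask), d[1:2]))
  gv <- unclass(g)
  attributes(gv) <- list(dim = d)
  N <- grow_neighborhood(Q)
  pool_q <- which(array(rep(Q$mask, d[3]), d))
  pool_n <- which(array(rep(N$mask, d[3]), d))
  if (sum(gv[pool_q]) <= 0) stop("zero-activation segment")
  p_q <- numeric(n_subsets)
  p_n <- numeric(n_subsets)
  with_seed(seed, {
    for (i in seq_len(n_subsets)) {
      iq <- sample_pool(pool_q, subset_size)
      il <- sample_pool(pool_n, subset_size)
      wq <- sum(gv[iq])
      wn <- sum(gv[il])
      p_q[i] <- if (wq > 0) Mod(sum(gv[iq] * exp(1i * phi[iq]))) / wq
                else NA_real_
      p_n[i] <- if (wn > 0) Mod(sum(gv[il] * exp(1i * phi[il]))) / wn
                else NA_real_
    }
  })
  kappa <- mean(p_q, na.rm = TRUE) - mean(p_n, na.rm = TRUE)
  attr(kappa, "p_Q") <- p_q
  attr(kappa, "p_N") <- p_n
  kappa
}

# In-mask cells with an in-grid 4-neighbor outside the mask.
boundary_cells <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  outside <- matrix(FALSE, nr, nc)
  outside[-nr, ] <- outside[-nr, ] | !mask[-1L, ]
  outside[-1L, ] <- outside[-1L, ] | !mask[-nr, ]
  outside[, -nc] <- outside[, -nc] | !mask[, -1L]
  outside[, -1L] <- outside[, -1L] | !mask[, -nc]
  which(mask & outside, arr.ind = TRUE)
}

# Local boundary tangent at (row, col): principal axis of the boundary
# cells within `radius`, as an angle in radians (x = columns, y = rows).
boundary_tangent <- function(bcells, center, radius) {
  dr <- bcells[, 1L] - center[1L]
  dc <- bcells[, 2L] - center[2L]
  near <- dr^2 + dc^2 <= radius^2
  if (sum(near) < 2L) return(NA_real_)
  m <- cbind(dc[near], dr[near])  # (x, y)
  cv <- crossprod(sweep(m, 2L, colMeans(m)))
  eg <- eigen(cv, symmetric = TRUE)
  atan2(eg$vectors[2L, 1L], eg$vectors[1L, 1L])
}

#' Semicircle phase contrast at segment boundaries
#'
#' At random boundary locations of `Q`, splits the disc of the given
#' radius along the local boundary tangent into an inner and an outer
#' semicircle (inner = the side containing more of the segment) and
#' measures the absolute wrapped difference between the two semicircles'
#' weighted circular mean phases, averaged over locations.
#'
#' @param map A [mean_phase_map()] result.
#' @param Q A [segment_mask()].
#' @param radius Disc radius in grid units (default 10).
#' @param n_locations Number of sampled boundary locations (default 50).
#' @param seed Sampling seed.
#' @return List with `mean` difference (radians), per-location `diff`,
#'   and `n_failed` (locations without valid cells in a semicircle,
#'   resampled).
#' @export
boundary_phase_difference <- function(map, Q, radius = 10L,
                                      n_locations = 50L, seed = 1L) {
  bc <- boundary_cells(Q$mask)
  if (nrow(bc) < 1L) stop("segment has no boundary cells")
  nr <- nrow(Q$mask); nc <- ncol(Q$mask)
  z <- map$weight * exp(1i * map$phi_avg)
  z[!map$valid] <- 0
  diffs <- numeric(0)
  n_failed <- 0L
  with_seed(seed, {
    n_draws <- min(4L * n_locations, 1000L)
    draws <- sample.int(nrow(bc), n_draws, replace = nrow(bc) < n_draws)
    for (li in draws) {
      if (length(diffs) >= n_locations) break
      ctr <- bc[li, ]
      ang <- boundary_tangent(bc, ctr, radius)
      if (is.na(ang)) { n_failed <- n_failed + 1L; next }
      nrm <- c(-sin(ang), cos(ang))  # unit normal (x, y)
      rows <- max(1L, ctr[1L] - radius):min(nr, ctr[1L] + radius)
      cols <- max(1L, ctr[2L] - radius):min(nc, ctr[2L] + radius)
      rg <- expand.grid(r = rows, c = cols)
      d2 <- (rg$r - ctr[1L])^2 + (rg$c - ctr[2L])^2
      rg <- rg[d2 < radius^2, ]
      side <- (rg$c - ctr[2L]) * nrm[1L] + (rg$r - ctr[1L]) * nrm[2L] > 0
      idx <- cbind(rg$r, rg$c)
      in_q <- Q$mask[idx]
      inner <- if (mean(in_q[side]) >= mean(in_q[!side])) side else !side
      z_in <- sum(z[idx[inner, , drop = FALSE]])
      z_out <- sum(z[idx[!inner, , drop = FALSE]])
      if (Mod(z_in) < 1e-12 || Mod(z_out) < 1e-12) {
        n_failed <- n_failed + 1L
        next
      }
      diffs <- c(diffs, abs(wrap_diff(Arg(z_in) - Arg(z_out))))
    }
  })
  list(mean = mean(diffs), diff = diffs, n_failed = n_failed)
}

#' Local variance in phase
#'
#' `theta[x,y] = 1 - |sum_k (phasor + its 4 nearest-neighbor phasors)| /
#' (5 K)`; at grid borders missing neighbors are dropped and the
#' normalizer reduced accordingly. Zero for a globally constant phase
#' field; large across phase discontinuities.
#'
#' @param phi Phase array `X x Y x K`.
#' @return Matrix `X x Y` in `[0, 1]`.
#' @export
local_phase_variance <- function(phi) {
  d <- dim(phi)
  nr <- d[1]; nc <- d[2]
  zk <- matrix(complex(modulus = 1, argument = phi), nr * nc, d[3])
  z <- matrix(rowSums(zk), nr, nc)
  acc <- z
  cnt <- matrix(1, nr, nc)
  acc[-1L, ] <- acc[-1L, ] + z[-nr, ]; cnt[-1L, ] <- cnt[-1L, ] + 1
  acc[-nr, ] <- acc[-nr, ] + z[-1L, ]; cnt[-nr, ] <- cnt[-nr, ] + 1
  acc[, -1L] <- acc[, -1L] + z[, -nc]; cnt[, -1L] <- cnt[, -1L] + 1
  acc[, -nc] <- acc[, -nc] + z[, -1L]; cnt[, -nc] <- cnt[, -nc] + 1
  1 - Mod(acc) / (cnt * d[3])
}

# Central-difference gradient of a matrix; one-sided at the borders.
# Returns list(gx, gy) with x along columns, y along rows.
grad2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- matrix(0, nr, nc)
  gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
  gx[, 1L] <- m[, 2L] - m[, 1L]
  gx[, nc] <- m[, nc] - m[, nc - 1L]
  gy[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
  gy[1L, ] <- m[2L, ] - m[1L, ]
  gy[nr, ] <- m[nr, ] - m[nr - 1L, ]
  list(gx = gx, gy = gy)
}

#' Boundary-angle estimation error from the phase map
#'
#' Estimates the local boundary orientation at sampled boundary
#' locations from the structure tensor of the local phase variance
#' (Gaussian window), taking the eigenvector of the smaller eigenvalue
#' (the gradient points across the boundary, so the minor axis runs
#' along it), and reports the mean absolute angular error against the
#' true mask tangent, folded to `[0, 90]` degrees.
#'
#' @param phi Phase array `X x Y x K`.
#' @param Q A [segment_mask()].
#' @param n_locations Number of sampled boundary locations (default 50).
#' @param window_sigma Gaussian window standard deviation in grid units
#'   (default 3).
#' @param tangent_radius Radius for the true-tangent fit (default 10).
#' @param seed Sampling seed.
#' @return List with `mean_error_deg`, per-location `errors_deg`, and
#'   `n_excluded` (degenerate structure tensors).
#' @export
boundary_angle_error <- function(phi, Q, n_locations = 50L,
                                 window_sigma = 3, tangent_radius = 10L,
                                 seed = 1L) {
  theta <- local_phase_variance(phi)
  gr <- grad2(theta)
  j11 <- gauss_smooth(gr$gx * gr$gx, window_sigma)
  j12 <- gauss_smooth(gr$gx * gr$gy, window_sigma)
  j22 <- gauss_smooth(gr$gy * gr$gy, window_sigma)
  bc <- boundary_cells(Q$mask)
  if (nrow(bc) < 1L) stop("segment has no boundary cells")
  errors <- numeric(0)
  n_excluded <- 0L
  with_seed(seed, {
    n_draws <- min(4L * n_locations, 1000L)
    draws <- sample.int(nrow(bc), n_draws, replace = nrow(bc) < n_draws)
    for (li in draws) {
      if (length(errors) >= n_locations) break
      ctr <- bc[li, ]
      true_ang <- boundary_tangent(bc, ctr, tangent_radius)
      if (is.na(true_ang)) { n_excluded <- n_excluded + 1L; next }
      J <- matrix(c(j11[ctr[1L], ctr[2L]], j12[ctr[1L], ctr[2L]],
                    j12[ctr[1L], ctr[2L]], j22[ctr[1L], ctr[2L]]), 2L)
      if (sum(abs(J)) < 1e-14) { n_excluded <- n_excluded + 1L; next }
      eg <- eigen(J, symmetric = TRUE)
      v <- eg$vectors[, 2L]  # eigenvector of the smaller eigenvalue
      est_ang <- atan2(v[2L], v[1L])
      err <- abs((est_ang - true_ang + pi / 2) %% pi - pi / 2)
      errors <- c(errors, err * 180 / pi)
    }
  })
  list(mean_error_deg = mean(errors), errors_deg = errors,
       n_excluded = n_excluded)
}

#' Paired matching versus non-matching comparison
#'
#' Paired differences between a metric evaluated with each mask on its
#' own simulation (matching) and on a different scene's simulation
#' (non-matching, deterministic derangement pairing), with a
#' normal-approximation 95% confidence interval.
#'
#' @param results_matching,results_nonmatching Numeric vectors of equal
#'   length, same segment order.
#' @return List with `diff`, `mean`, `ci` (`c(lower, upper)`), and `n`.
#' @export
matching_baseline <- function(results_matching, results_nonmatching) {
  if (length(results_matching) != length(results_nonmatching))
    stop("mismatched mask sets between conditions")
  d <- as.numeric(results_matching) - as.numeric(results_nonmatching)
  n <- sum(!is.na(d))
  m <- mean(d, na.rm = TRUE)
  sem <- sd(d, na.rm = TRUE) / sqrt(n)
  list(diff = d, mean = m, ci = c(m - 1.96 * sem, m + 1.96 * sem), n = n)
}
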