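#' Simulation configuration for the coupled phase oscillators
#'
#' One "iteration" is one classical Runge-Kutta step of unit step size;
#' the interaction time scale `tau` absorbs all time units. The natural
#' frequency is eliminated from the dynamics (the phase variables are
#' offsets relative to the global oscillation) and is carried only as
#' documentation.
#'
#' @param tau Interaction time scale (> 0); 1/3 is the reference value
#'   for Gabor activations, 1/30 for autoencoder activations.
#' @param n_iterations Number of unit RK4 steps (default 20).
#' @param seed Seed for the uniform random initial phases.
#' @param wrap Toroidal grid (default `FALSE`: sources outside the grid
#'   contribute nothing).
#' @param snapshot_every Store every n-th iterate (default 1).
#' @param omega Natural frequency, documentation only (default 0).
#' @return A `sim_config` list.
#' @export
sim_config <- function(tau = 1 / 3, n_iterations = 20L, seed = 1L,
                       wrap = FALSE, snapshot_every = 1L, omega = 0) {
  stopifnot(tau > 0, n_iterations >= 1L, snapshot_every >= 1L)
  structure(list(tau = tau, n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), wrap = wrap,
                 snapshot_every = as.integer(snapshot_every),
                 omega = omega),
            class = "sim_config")
}

#' Right-hand side of the activation-weighted Kuramoto network
#'
#' `dphi[x,y,k]/dt = -(1/tau) * sum_e g[x,y,k] * w_e * g[x-dx,y-dy,j] *
#' sin(phi[x,y,k] - phi[x-dx,y-dy,j])`, accumulated over the
#' translation-invariant connection templates. Inactive neurons
#' (`g = 0`) have zero derivative and contribute nothing to others;
#' source positions outside the grid contribute zero unless `wrap`.
#'
#' @param phi Phase array (`X x Y x K`, radians).
#' @param g An [activation_block()] at stage `"g"` (or a bare array).
#' @param conns A [connection_set()].
#' @param tau Interaction time scale.
#' @param wrap Toroidal boundary.
#' @return Rate array of the same shape.
#' @export
phase_derivative <- function(phi, g, conns, tau, wrap = FALSE) {
  stopifnot(identical(dim(phi), dim(g)))
  g <- unclass(g)
  attributes(g) <- list(dim = dim(g))
  cpp_phase_deriv(phi, g, as.integer(conns$dx), as.integer(conns$dy),
                  as.integer(conns$j), as.integer(conns$k),
                  as.numeric(conns$w), tau, wrap)
}

#' Simulate the coupled phase oscillator network
#'
#' Initial phases are i.i.d. uniform on `[0, 2 * pi)` (drawn
#' feature-major from the seed); activations are fixed for the whole run.
#' Each iteration is one classical 4th-order Runge-Kutta step of unit
#' step size, after which phases are wrapped back to `[0, 2 * pi)`.
#'
#' @param g An [activation_block()] at stage `"g"` (or a bare nonnegative
#'   array).
#' @param conns A [connection_set()].
#' @param config A [sim_config()].
#' @param phi0 Optional initial phase array (overrides the seeded draw).
#' @return A `phase_trajectory`: 4-d array `X x Y x K x n_snapshots`
#'   with an `iterations` attribute (iteration index of each snapshot,
#'   starting at 0) and the config attached.
#' @export
simulate_phases <- function(g, conns, config = sim_config(), phi0 = NULL) {
  d <- dim(g)
  K <- d[3]
  if (is.null(phi0)) {
    phi0 <- with_seed(config$seed, {
      fm <- array(runif(prod(d), 0, 2 * pi), c(K, d[1], d[2]))
      aperm(fm, c(2, 3, 1))  # feature-major draw order
    })
  }
  stopifnot(identical(dim(phi0), d))
  gv <- unclass(g)
  attributes(gv) <- list(dim = d)
  snaps <- seq(0L, config$n_iterations, by = config$snapshot_every)
  if (snaps[length(snaps)] != config$n_iterations)
    snaps <- c(snaps, config$n_iterations)
  traj <- array(NA_real_, c(d, length(snaps)))
  phi <- wrap_phase(phi0)
  traj[, , , 1L] <- phi
  si <- 2L
  deriv <- function(p) phase_derivative(p, gv, conns, config$tau,
                                        config$wrap)
  for (it in seq_len(config$n_iterations)) {
    k1 <- deriv(phi)
    k2 <- deriv(phi + 0.5 * k1)
    k3 <- deriv(phi + 0.5 * k2)
    k4 <- deriv(phi + k3)
    phi <- wrap_phase(phi + (k1 + 2 * k2 + 2 * k3 + k4) / 6)
    if (!all(is.finite(phi)))
      stop("non-finite phase at iteration ", it)
    if (it %in% snaps) {
      traj[, , , si] <- phi
      si <- si + 1L
    }
  }
  structure(traj, class = "phase_trajectory", iterations = snaps,
            config = config)
}

#' @export
print.phase_trajectory <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<phase_trajectory %dx%dx%d, %d snapshots (0..%d)>\n",
              d[1], d[2], d[3], d[4],
              max(attr(x, "iterations"))))
  invisible(x)
}

#' Final phase state of a trajectory
#' @param traj A `phase_trajectory`.
#' @return The last snapshot as an `X x Y x K` array.
#' @export
final_phases <- function(traj) {
  d <- dim(traj)
  array(traj[, , , d[4]], d[1:3])
}

#' Regular local connectivity for the pinwheel demonstration
#'
#' Synchronizing (+1) connections from every neighbor within Euclidean
#' distance `max_length` on a single feature map, no self-loop.
#'
#' @param max_length Maximum connection length in grid units.
#' @param n_features Number of feature maps (default 1; the same
#'   intra-feature pattern is applied to each).
#' @return A [connection_set()].
#' @export
make_local_connectivity <- function(max_length = 3L, n_features = 1L) {
  stopifnot(max_length >= 1)
  r <- ceiling(max_length)
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= max_length^2 &
                 !(offs$dx == 0 & offs$dy == 0), ]
  recs <- do.call(rbind, lapply(seq_len(n_features), function(f)
    data.frame(dx = offs$dx, dy = offs$dy, j = f, k = f, w = 1)))
  connection_set(recs, n_features = n_features)
}

#' Per-iteration step-size sanity criterion
#'
#' Fraction of neurons whose wrapped phase change between consecutive
#' snapshots exceeds `pi / 2`; a run passes when every iteration's
#' fraction is at most 1%.
#'
#' @param traj A `phase_trajectory` (snapshots at every iteration).
#' @param threshold Wrapped-change threshold (default `pi / 2`).
#' @param max_fraction Pass bound (default 0.01).
#' @return List with `fraction` per iteration interval and `pass`.
#' @export
check_step_criterion <- function(traj, threshold = pi / 2,
                                 max_fraction = 0.01) {
  d <- dim(traj)
  if (d[4] < 2L) stop("need >= 2 snapshots")
  frac <- numeric(d[4] - 1L)
  for (i in seq_len(d[4] - 1L)) {
    dphi <- wrap_diff(traj[, , , i + 1L] - traj[, , , i])
    frac[i] <- mean(abs(dphi) > threshold)
  }
  list(fraction = frac, pass = all(frac <= max_fraction))
}

#' Count phase singularities (pinwheels) in a phase map
#'
#' Sums wrapped phase differences around every 2 x 2 plaquette; a
#' winding of `+/- 2 * pi` marks a pinwheel center.
#'
#' @param phase_map Matrix of phases in radians.
#' @return List with `count` and the integer `winding` matrix.
#' @export
count_pinwheels <- function(phase_map) {
  a <- phase_map[-nrow(phase_map), -ncol(phase_map)]
  b <- phase_map[-nrow(phase_map), -1L]
  c_ <- phase_map[-1L, -1L]
  d <- phase_map[-1L, -ncol(phase_map)]
  tot <- wrap_diff(b - a) + wrap_diff(c_ - b) +
         wrap_diff(d - c_) + wrap_diff(a - d)
  winding <- round(tot / (2 * pi))
  list(count = sum(winding != 0), winding = winding)
}
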