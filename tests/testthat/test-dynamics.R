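# Plain-R reference implementation of the phase derivative, independent
# of the compiled path: explicit loops over neurons and templates.
ref_deriv <- function(phi, g, recs, tau) {
  d <- dim(phi)
  out <- array(0, d)
  for (e in seq_len(nrow(recs))) {
    for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
      sr <- r - recs$dy[e]
      sc <- cc - recs$dx[e]
      if (sr < 1 || sr > d[1] || sc < 1 || sc > d[2]) next
      k <- recs$k[e]; j <- recs$j[e]
      out[r, cc, k] <- out[r, cc, k] -
        (1 / tau) * g[r, cc, k] * recs$w[e] * g[sr, sc, j] *
        sin(phi[r, cc, k] - phi[sr, sc, j])
    }
  }
  out
}

test_that("phase derivative matches single-term arithmetic and fixed points", {
  st <- pair_state(0, pi / 2)
  conns <- connection_set(data.frame(dx = -1, dy = 0, j = 1, k = 1, w = 1),
                          n_features = 1L)
  d <- phase_derivative(st$phi, st$g, conns, tau = 1)
  # target neuron 1 drifts toward its source: -sin(0 - pi/2) = +1
  expect_equal(d[1, 1, 1], 1)
  expect_equal(d[1, 2, 1], 0)  # source out of grid

  # equal phases are a fixed point
  st2 <- pair_state(1.3, 1.3)
  expect_true(all(phase_derivative(st2$phi, st2$g, pair_conns(), 0.5) == 0))

  # inactive neurons: zero derivative and no contribution to others
  st3 <- pair_state(0, pi / 2, g1 = 1, g2 = 0)
  d3 <- phase_derivative(st3$phi, st3$g, pair_conns(), 1)
  expect_true(all(d3 == 0))
})

test_that("compiled derivative agrees with the loop reference on random instances", {
  phasebind:::with_seed(4, {
    for (rep in 1:3) {
      d <- c(5L, 6L, 3L)
      phi <- array(runif(prod(d), 0, 2 * pi), d)
      g <- array(runif(prod(d)), d)
      recs <- data.frame(dx = sample(-2:2, 15, TRUE),
                         dy = sample(-2:2, 15, TRUE),
                         j = sample(1:3, 15, TRUE),
                         k = sample(1:3, 15, TRUE),
                         w = sample(c(-1, 1), 15, TRUE))
      recs <- recs[!(recs$dx == 0 & recs$dy == 0 & recs$j == recs$k), ]
      conns <- connection_set(recs, n_features = 3L)
      expect_equal(phase_derivative(phi, activation_block(g, "g"), conns,
                                    0.7),
                   ref_deriv(phi, g, recs, 0.7), tolerance = 1e-12)
    }
  })
})

test_that("unit-step RK4 tracks a dense-step reference integrator", {
  # 10 oscillators on a 1 x 10 grid, random sparse coupling
  phasebind:::with_seed(5, {
    d <- c(1L, 10L, 1L)
    g <- array(runif(10, 0.2, 1), d)
    g <- g / sum(g) * 10 / 3  # moderate activation scale
    recs <- data.frame(dx = sample(c(-3:-1, 1:3), 14, TRUE), dy = 0,
                       j = 1, k = 1, w = sample(c(-1, 1, 1), 14, TRUE))
    phi0 <- array(runif(10, 0, 2 * pi), d)
  })
  conns <- connection_set(recs, n_features = 1L)
  gb <- activation_block(g, "g")
  traj <- simulate_phases(gb, conns, sim_config(tau = 1, n_iterations = 20L,
                                                seed = 1L,
                                                snapshot_every = 20L),
                          phi0 = phi0)
  # reference: plain-R RK4 at step 1/100
  h <- 1 / 100
  phi <- phi0
  for (step in seq_len(20L / h)) {
    k1 <- ref_deriv(phi, g, recs, 1)
    k2 <- ref_deriv(phi + h / 2 * k1, g, recs, 1)
    k3 <- ref_deriv(phi + h / 2 * k2, g, recs, 1)
    k4 <- ref_deriv(phi + h * k3, g, recs, 1)
    phi <- phi + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  dev <- abs(phasebind:::wrap_diff(final_phases(traj) - phi))
  expect_lt(max(dev), 1e-3)
})

test_that("global phase-shift equivariance and frozen inactive phases", {
  phasebind:::with_seed(6, {
    d <- c(6L, 6L, 2L)
    g <- array(runif(prod(d)), d)
    g[2, 3, ] <- 0  # one inactive position
    recs <- data.frame(dx = sample(-2:2, 20, TRUE),
                       dy = sample(-2:2, 20, TRUE),
                       j = sample(1:2, 20, TRUE),
                       k = sample(1:2, 20, TRUE),
                       w = sample(c(-1, 1), 20, TRUE))
    phi0 <- array(runif(prod(d), 0, 2 * pi), d)
  })
  recs <- recs[!(recs$dx == 0 & recs$dy == 0 & recs$j == recs$k), ]
  conns <- connection_set(recs, n_features = 2L)
  gb <- activation_block(g, "g")
  cfg <- sim_config(tau = 0.5, n_iterations = 10L, seed = 1L,
                    snapshot_every = 10L)
  t1 <- simulate_phases(gb, conns, cfg, phi0 = phi0)
  shift <- 1.234
  t2 <- simulate_phases(gb, conns, cfg, phi0 = phi0 + shift)
  dev <- abs(phasebind:::wrap_diff(final_phases(t2) -
                                     final_phases(t1) - shift))
  expect_lt(max(dev), 1e-9)

  # inactive position keeps its initial phase through the whole run
  expect_equal(final_phases(t1)[2, 3, ],
               phasebind:::wrap_phase(phi0[2, 3, ]))
})

test_that("a mutually coupled pair contracts monotonically to synchrony", {
  st <- pair_state(0.5, 2.5)
  traj <- simulate_phases(st$g, pair_conns(),
                          sim_config(tau = 4, n_iterations = 60L, seed = 1L),
                          phi0 = st$phi)
  gaps <- abs(phasebind:::wrap_diff(traj[1, 1, 1, ] - traj[1, 2, 1, ]))
  expect_true(all(diff(gaps) < 0 | gaps[-1] < 1e-6))
  expect_lt(gaps[length(gaps)], 1e-6)
})

test_that("symmetric coupling descends the interaction potential", {
  phasebind:::with_seed(7, {
    d <- c(5L, 5L, 2L)
    g <- array(runif(prod(d), 0.1, 1), d)
    g <- g / max(g) / 4
    half <- data.frame(dx = sample(-2:2, 10, TRUE),
                       dy = sample(-2:2, 10, TRUE),
                       j = sample(1:2, 10, TRUE),
                       k = sample(1:2, 10, TRUE),
                       w = sample(c(-1, 1), 10, TRUE))
  })
  half <- half[!(half$dx == 0 & half$dy == 0 & half$j == half$k), ]
  sym <- rbind(half, data.frame(dx = -half$dx, dy = -half$dy,
                                j = half$k, k = half$j, w = half$w))
  conns <- connection_set(sym, n_features = 2L)
  gb <- activation_block(g, "g")
  potential <- function(phi) {
    v <- 0
    for (e in seq_len(nrow(sym))) {
      for (r in 1:5) for (cc in 1:5) {
        sr <- r - sym$dy[e]; sc <- cc - sym$dx[e]
        if (sr < 1 || sr > 5 || sc < 1 || sc > 5) next
        v <- v - g[r, cc, sym$k[e]] * sym$w[e] * g[sr, sc, sym$j[e]] *
          cos(phi[r, cc, sym$k[e]] - phi[sr, sc, sym$j[e]])
      }
    }
    v
  }
  traj <- simulate_phases(gb, conns, sim_config(tau = 1,
                                                n_iterations = 30L,
                                                seed = 2L))
  expect_true(check_step_criterion(traj)$pass)
  vals <- vapply(seq_len(dim(traj)[4]), function(i)
    potential(array(traj[, , , i], dim(traj)[1:3])), numeric(1L))
  expect_true(all(diff(vals) <= 1e-8))
})

test_that("step criterion separates quiet and violent trajectories", {
  st <- pair_state(0.3, 0.3)
  quiet <- simulate_phases(st$g, pair_conns(),
                           sim_config(tau = 2, n_iterations = 5L, seed = 1L),
                           phi0 = st$phi)
  crit <- check_step_criterion(quiet)
  expect_true(crit$pass)
  expect_true(all(crit$fraction == 0))

  # tau -> 0 on a coupled pair at pi/2 separation: everything jumps
  st2 <- pair_state(0, pi / 2)
  wild <- simulate_phases(st2$g, pair_conns(),
                          sim_config(tau = 0.01, n_iterations = 3L,
                                     seed = 1L), phi0 = st2$phi)
  expect_false(check_step_criterion(wild)$pass)
  expect_gt(max(check_step_criterion(wild)$fraction), 0.5)
})

test_that("local connectivity neighborhoods enumerate correctly", {
  c1 <- make_local_connectivity(1)
  expect_identical(nrow(c1), 4L)  # 4-neighborhood only: sqrt(2) > 1
  expect_true(all(abs(c1$dx) + abs(c1$dy) == 1))
  c3 <- make_local_connectivity(3)
  expect_identical(nrow(c3), 28L)
  expect_true(all(c3$dx^2 + c3$dy^2 <= 9))
  expect_true(all(c3$w == 1))
})

test_that("winding-number pinwheel counter flags singularities", {
  # an ideal +1 vortex field
  n <- 21L
  xs <- matrix(rep(seq_len(n) - 11, each = n), n)
  ys <- matrix(rep(seq_len(n) - 11, n), n)
  vortex <- phasebind:::wrap_phase(atan2(ys + 0.5, xs + 0.5))
  pw <- count_pinwheels(vortex)
  expect_identical(pw$count, 1L)
  expect_equal(sum(pw$winding), 1)
  # constant map has none
  expect_identical(count_pinwheels(matrix(1.1, 10, 10))$count, 0L)
})

test_that("the reference tau passes the step criterion on a scene fixture", {
  bank <- build_gabor_bank(color = FALSE)
  sc <- make_synthetic_scene(77L, n_segments = 2L, extent = 96L)
  pre <- preprocess_image(sc$image, target = c(96L, 96L))
  g <- regularize_activations(forward_activations(pre, bank))
  conns <- make_local_connectivity(2L, n_features = dim(g)[3])
  traj <- simulate_phases(g, conns, sim_config(tau = 1 / 3,
                                               n_iterations = 10L,
                                               seed = 1L))
  expect_true(check_step_criterion(traj)$pass)
})
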