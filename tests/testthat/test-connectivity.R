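# Hand-built correlation tensor for sampler and FDR tests.
craft_ct <- function(rho, n_samples) {
  K <- dim(rho)[1]
  D <- dim(rho)[3]
  M <- (D - 1L) %/% 2L
  structure(list(rho = rho, offsets = -M:M,
                 n = matrix(n_samples, D, D), sig = !is.na(rho),
                 max_offset = M),
            class = "correlation_tensor")
}

test_that("correlation tensor reproduces constructed correlations", {
  phasebind:::with_seed(1, {
    v1 <- matrix(rnorm(60 * 60), 60)
    v2 <- cbind(matrix(rnorm(60 * 3), 60), v1[, 1:57])  # f1 shifted by +3 cols
    a <- array(c(v1, v2), c(60, 60, 2))
  })
  ct <- correlation_tensor(activation_block(abs(a), "h"), max_offset = 4L)
  ix <- function(d) d + 5L
  expect_equal(ct$rho[1, 1, ix(0), ix(0)], 1)
  expect_equal(ct$rho[2, 2, ix(0), ix(0)], 1)
  expect_equal(ct$rho[1, 2, ix(3), ix(0)], 1, tolerance = 1e-12)

  # symmetry rho[k,m,d] == rho[m,k,-d]
  for (k in 1:2) for (m in 1:2) for (dx in -4:4) for (dy in -4:4)
    expect_equal(ct$rho[k, m, ix(dx), ix(dy)],
                 ct$rho[m, k, ix(-dx), ix(-dy)], tolerance = 1e-12)
})

test_that("independent noise features stay within the null envelope", {
  phasebind:::with_seed(2, {
    a <- array(abs(rnorm(104 * 104 * 2)), c(104, 104, 2))
  })
  ct <- correlation_tensor(activation_block(a, "h"), max_offset = 2L)
  off_diag <- abs(ct$rho[1, 2, , ])
  n <- min(ct$n)
  expect_gte(mean(off_diag < 4 / sqrt(n)), 0.99)
})

test_that("BHY masking agrees with the p.adjust oracle and its limit cases", {
  # mixed random correlations: compare the mask entry-by-entry with
  # stats::p.adjust(method = "BY")
  phasebind:::with_seed(3, {
    rho <- array(runif(3 * 3 * 9, -0.4, 0.4), c(3, 3, 3, 3))
  })
  n <- 120L
  ct <- fdr_significance_mask(craft_ct(rho, n), q = 0.05)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * pt(-abs(tt), df = n - 2)
  oracle <- array(p.adjust(p, method = "BY") <= 0.05, dim(rho))
  expect_identical(ct$sig, oracle)

  # strong correlations everywhere: everything retained
  strong <- fdr_significance_mask(craft_ct(array(0.9, c(2, 2, 3, 3)),
                                           200L), q = 0.05)
  expect_true(all(strong$sig))

  # 100 tests: 10 forced near-zero p (self correlations), 90 at p = 0.5;
  # the p = 0.5 block must not survive the step-up
  rho2 <- array(0, c(10, 10, 1, 1))
  t_half <- qt(0.75, df = 98)
  rho2[, , 1, 1] <- t_half / sqrt(98 + t_half^2)
  for (k in 1:10) rho2[k, k, 1, 1] <- 1 - 1e-12
  ct2 <- fdr_significance_mask(craft_ct(rho2, 100L), q = 0.05)
  expect_true(all(diag(ct2$sig[, , 1, 1])))
  expect_false(any(ct2$sig[, , 1, 1][upper.tri(rho2[, , 1, 1])]))
})

test_that("connection sampling respects signs, counts and exhaustive pools", {
  # one feature, offsets +/-1: 8 non-self candidates
  rho <- array(0, c(1, 1, 3, 3))
  rho[1, 1, , ] <- matrix(c(0.3, -0.2, 0.3,
                            -0.2, 1,  0.3,
                            0.3,  0.3, 0.3), 3, byrow = TRUE)
  ct <- craft_ct(rho, 100L)
  cs <- sample_connections(ct, eta_plus = 6L, eta_minus = 2L, seed = 1L)
  expect_identical(nrow(cs), 8L)
  # exhaustive pools: every positive candidate sampled exactly once
  sync <- cs[cs$w > 0, ]
  expect_identical(nrow(sync), 6L)
  expect_false(any(duplicated(sync[c("dx", "dy", "j")])))
  for (i in seq_len(nrow(cs))) {
    r <- cs[i, ]
    expect_identical(sign(rho[r$j, r$k, r$dx + 2L, r$dy + 2L]),
                     r$w)
  }
  # no self-loop possible even with eta at the pool size
  expect_false(any(cs$dx == 0 & cs$dy == 0 & cs$j == cs$k))

  # determinism
  expect_identical(as.data.frame(sample_connections(ct, 6L, 2L, seed = 9L)),
                   as.data.frame(sample_connections(ct, 6L, 2L, seed = 9L)))

  expect_error(sample_connections(ct, eta_plus = 7L, eta_minus = 2L),
               "insufficient")
})

test_that("inclusion frequencies match the capped proportional probabilities", {
  # 6 positive candidates with unequal weights, eta_plus = 2
  w <- c(0.05, 0.1, 0.15, 0.2, 0.25, 0.25)
  rho <- array(0, c(1, 1, 3, 3))
  rho[1, 1, , ] <- matrix(c(w[1], -0.5, w[2],
                            -0.5, 1, w[3],
                            w[4], w[5], w[6]), 3, byrow = TRUE)
  ct <- craft_ct(rho, 100L)
  # independent oracle: capped proportional inclusion probabilities
  expected <- local({
    p <- 2 * w / sum(w)
    stopifnot(all(p < 1))  # no capping needed for this instance
    p
  })
  n_rep <- 1000L
  hits <- numeric(6L)
  # the crafted matrix is filled with byrow = TRUE, so rows index dx and
  # columns index dy: weights w1..w6 live at these (dx, dy) offsets
  key <- function(df) paste(df$dx, df$dy)
  wkey <- c("-1 -1", "-1 1", "0 1", "1 -1", "1 0", "1 1")
  for (s in seq_len(n_rep)) {
    cs <- sample_connections(ct, eta_plus = 2L, eta_minus = 1L, seed = s)
    hits <- hits + (wkey %in% key(cs[cs$w > 0, ]))
  }
  freq <- hits / n_rep
  se <- sqrt(expected * (1 - expected) / n_rep)
  expect_true(all(abs(freq - expected) <= 3 * se))
})

test_that("connection sparsity arithmetic matches full-connectivity accounting", {
  expect_equal(round(connection_sparsity(200, 200, 200, 150, 48), 3), 0.014)
  expect_equal(round(connection_sparsity(200, 200, 200, 150, 100), 3), 0.007)
  expect_equal(connection_sparsity(100, 92, 4, 4, 6), 100)
})

test_that("anisotropy rings follow the lattice geometry", {
  K <- 2L
  M <- 3L
  D <- 2L * M + 1L
  offs <- -M:M
  dist <- sqrt(outer(offs^2, offs^2, `+`))
  ring_only <- array(0, c(K, K, D, D))
  for (i in seq_len(D)) for (j in seq_len(D))
    ring_only[, , i, j] <- 0.5 / (1 + round(dist[i, j]))
  ct <- craft_ct(ring_only, 50L)
  prof <- anisotropy_profile(ct)
  expect_identical(prof$n_offsets[prof$r == 0], 1L)
  expect_identical(prof$n_offsets[prof$r == 1], 8L)
  expect_true(all(abs(prof$anisotropy[prof$r >= 1]) < 1e-12))

  varying <- ring_only
  varying[1, 1, M + 2L, M + 1L] <- 0.9  # break the ring symmetry at r = 1
  prof2 <- anisotropy_profile(craft_ct(varying, 50L))
  expect_gt(prof2$anisotropy[prof2$r == 1], 0)
})

test_that("clustering, paths and intra-feature fraction on analytic graphs", {
  # complete 3-feature column at zero offset
  cmb <- expand.grid(j = 1:3, k = 1:3)
  cmb <- cmb[cmb$j != cmb$k, ]
  full <- connection_set(data.frame(dx = 0, dy = 0, j = cmb$j, k = cmb$k,
                                    w = 1), n_features = 3L)
  gm <- graph_metrics(full, "sync", seed = 1L, n_random = 2L)
  expect_equal(gm$gamma, 1)
  expect_equal(gm$lambda_path, 1)

  # triangle-free chain 1 -> 2 -> 3
  chain <- connection_set(data.frame(dx = 0, dy = 0, j = c(1, 2),
                                     k = c(2, 3), w = 1), n_features = 3L)
  gm2 <- suppressWarnings(graph_metrics(chain, "sync", seed = 1L,
                                        n_random = 2L))
  expect_equal(gm2$gamma, 0)

  # 2 intra- + 8 inter-feature connections: mu = 25%
  recs <- data.frame(dx = c(1, 2, rep(1, 8)), dy = 0,
                     j = c(1, 2, rep(1:4, 2)),
                     k = c(1, 2, rep(c(2:4, 1), 2)), w = 1)
  mu_set <- connection_set(recs, n_features = 4L)
  gm3 <- suppressWarnings(graph_metrics(mu_set, "sync", seed = 1L,
                                        n_random = 2L))
  expect_equal(gm3$mu, 25)
})

test_that("bounded column BFS agrees with an explicit igraph lattice", {
  skip_if_not_installed("igraph")
  phasebind:::with_seed(8, {
    recs <- data.frame(dx = sample(-2:2, 12, TRUE),
                       dy = sample(-2:2, 12, TRUE),
                       j = sample(1:3, 12, TRUE),
                       k = sample(1:3, 12, TRUE), w = 1)
  })
  recs <- recs[!(recs$dx == 0 & recs$dy == 0 & recs$j == recs$k), ]
  K <- 3L
  B <- 6L
  ours <- phasebind:::path_lengths_column(recs, K, bound = B,
                                          max_hops = 10L)
  # unrolled finite lattice with the same templates
  coords <- expand.grid(x = -B:B, y = -B:B, f = seq_len(K))
  id <- function(f, x, y) which(coords$f == f & coords$x == x &
                                  coords$y == y)
  edges <- integer(0)
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    ok <- coords$f == r$j & abs(coords$x + r$dx) <= B &
      abs(coords$y + r$dy) <= B
    from <- which(ok)
    to <- vapply(from, function(n) id(r$k, coords$x[n] + r$dx,
                                      coords$y[n] + r$dy), integer(1L))
    edges <- c(edges, rbind(from, to))
  }
  gr <- igraph::make_graph(edges, n = nrow(coords), directed = TRUE)
  for (s in seq_len(K)) {
    d_ig <- igraph::distances(gr, v = id(s, 0, 0),
                              to = vapply(seq_len(K), function(f)
                                id(f, 0, 0), integer(1L)),
                              mode = "out")
    d_ig[is.infinite(d_ig)] <- NA_real_
    d_ig[s] <- NA_real_
    expect_equal(unname(ours[s, ]), as.numeric(d_ig))
  }
})
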