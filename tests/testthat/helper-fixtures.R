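# Shared fixtures, built in code at test time.

# Small preprocessed white-noise image.
noise_image <- function(seed, n = 48L) {
  with_seed <- phasebind:::with_seed
  with_seed(seed, image_rgb(array(rnorm(n * n * 3), c(n, n, 3L)), "raw"))
}

# A tiny trained-scene world shared by the connectivity tests: cached in
# the session so several test files can reuse it.
desk_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bank <- build_gabor_bank(color = FALSE)
      imgs <- lapply(1:4, function(i)
        make_synthetic_scene(9000 + i, extent = 96L)$image)
      cache <<- learn_connectivity(imgs, bank, eta_plus = 30L,
                                   eta_minus = 30L, max_offset = 5L,
                                   seed = 42L)
    }
    cache
  }
})

# Reference logistic map activations for dynamics tests: a two-neuron
# grid with one feature.
pair_state <- function(phi1, phi2, g1 = 1, g2 = 1) {
  g <- activation_block(array(c(g1, g2), c(1L, 2L, 1L)), "g")
  phi <- array(c(phi1, phi2), c(1L, 2L, 1L))
  list(g = g, phi = phi)
}

# Mutual sync coupling between the two neurons of pair_state
# (offset +/-1 along columns).
pair_conns <- function() {
  connection_set(data.frame(dx = c(1, -1), dy = 0, j = 1, k = 1,
                            w = 1), n_features = 1L)
}
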