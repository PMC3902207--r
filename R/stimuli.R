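#' Generate an artificial test stimulus
#'
#' Grayscale demonstration stimuli replicated over the three color
#' channels: a uniform field, two collinear bars separated by a gap, or a
#' dashed circle (arc segments with gaps). Foreground is dark (0) on a
#' light (1) background.
#'
#' @param kind `"uniform"`, `"collinear_bars"` or `"dashed_circle"`.
#' @param extent Image side length in pixels (square image).
#' @return A raw [image_rgb()].
#' @export
make_artificial_stimulus <- function(kind = c("uniform", "collinear_bars",
                                              "dashed_circle"),
                                     extent = 128L) {
  kind <- match.arg(kind)
  extent <- as.integer(extent)
  if (extent < 16L) stop("`extent` must be at least 16 pixels")
  m <- matrix(1, extent, extent)
  if (kind == "uniform") {
    m[] <- 0.5
  } else if (kind == "collinear_bars") {
    th <- max(2L, round(extent / 24))
    len <- round(extent / 4)
    gap <- round(extent / 8)
    rows <- (extent %/% 2L - th %/% 2L) + seq_len(th) - 1L
    left_end <- extent %/% 2L - gap %/% 2L
    right_start <- extent %/% 2L + gap %/% 2L + gap %% 2L
    m[rows, (left_end - len + 1L):left_end] <- 0
    m[rows, right_start:(right_start + len - 1L)] <- 0
  } else {
    radius <- extent / 3
    th <- max(2L, round(extent / 24))
    cx <- (extent + 1) / 2
    xs <- matrix(rep(seq_len(extent), each = extent), extent)
    ys <- matrix(rep(seq_len(extent), extent), extent)
    r <- sqrt((xs - cx)^2 + (ys - cx)^2)
    ang <- (atan2(ys - cx, xs - cx) %% (2 * pi)) / pi * 180
    # 8 arcs of 30 degrees separated by 15-degree gaps
    on_arc <- (ang %% 45) < 30
    m[abs(r - radius) < th / 2 & on_arc] <- 0
  }
  image_rgb(m, "raw")
}

# Smoothed Gaussian noise field, roughly 1/f-like, for scene textures.
texture_field <- function(extent, sigma, sd) {
  gauss_smooth(matrix(rnorm(extent * extent, sd = sd), extent), sigma) *
    (sigma + 1)  # undo most of the smoothing attenuation
}

# Oriented band-limited texture: a grating at a random orientation and
# wavelength with spatially jittered phase, emulating the dominant local
# orientation structure of natural surfaces.
oriented_texture <- function(extent, angle, wavelength, amplitude,
                             jitter_sd = 0.8) {
  xs <- matrix(rep(seq_len(extent), each = extent), extent)
  ys <- matrix(rep(seq_len(extent), extent), extent)
  jitter <- gauss_smooth(matrix(rnorm(extent * extent, sd = jitter_sd),
                                extent), 4) * 5
  amplitude * sin(2 * pi * (xs * cos(angle) + ys * sin(angle)) /
                    wavelength + jitter)
}

# Random smooth blob-like polygon around a center, in pixel
# coordinates: many vertices with a low-order Fourier radius
# perturbation, so boundaries curve smoothly the way natural object
# outlines do (smooth curvature is what teaches the connectivity to
# link neighboring orientations).
random_polygon <- function(cx, cy, radius, n_vertices = 16L) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  ang <- ang + runif(1, 0, 2 * pi / n_vertices)
  rad <- radius * (0.85 +
                     0.12 * cos(ang + runif(1, 0, 2 * pi)) +
                     0.08 * cos(2 * ang + runif(1, 0, 2 * pi)))
  cbind(x = cx + rad * cos(ang), y = cy + rad * sin(ang))
}

#' Generate a synthetic natural-like scene with ground-truth masks
#'
#' Stands in for hand-labeled photographs: a textured colored background
#' carrying `n_segments` non-overlapping textured convex polygonal
#' segments whose mean color differs from the background by at least
#' `contrast` per channel. Masks are rasterized onto the neuron grid
#' (pixel coordinates divided by `stride`) and are guaranteed, by the
#' choice of segment radii, to fall in the evaluated size range.
#'
#' @param seed Integer; the same seed reproduces the identical scene.
#' @param n_segments Number of segments (>= 1).
#' @param extent Image side length in pixels.
#' @param contrast Minimum per-channel absolute color offset between a
#'   segment and the background (default 0.25).
#' @param stride Forward-projection stride defining the neuron grid
#'   (default 2).
#' @return A `scene_fixture`: list with `image` (raw [image_rgb()]),
#'   `masks` (list of [segment_mask()] on the neuron grid), `seed`, and
#'   the generator parameters.
#' @export
make_synthetic_scene <- function(seed, n_segments = 3L, extent = 128L,
                                 contrast = 0.25, stride = 2L) {
  stopifnot(n_segments >= 1L)
  extent <- as.integer(extent)
  if (extent < 16L * n_segments %/% 2L + 32L)
    stop("`extent` too small to place ", n_segments, " segments")
  with_seed(seed, {
    base_col <- runif(3, 0.35, 0.65)
    px <- array(0, c(extent, extent, 3L))
    # backgrounds (sky, road, walls) carry mostly smooth low-amplitude
    # structure; objects get the stronger oriented surface texture below
    bg_tex <- texture_field(extent, sigma = 3, sd = 0.04) +
      oriented_texture(extent, runif(1, 0, pi), runif(1, 8, 16), 0.04)
    for (ch in 1:3) px[, , ch] <- base_col[ch] + bg_tex * runif(1, 0.6, 1)
    xs <- matrix(rep(seq_len(extent), each = extent), extent)
    ys <- matrix(rep(seq_len(extent), extent), extent)
    occupied <- matrix(FALSE, extent, extent)
    masks <- vector("list", n_segments)
    placed <- 0L
    attempts <- 0L
    while (placed < n_segments) {
      attempts <- attempts + 1L
      if (attempts > 200L)
        stop("`extent` too small to place ", n_segments, " segments")
      radius <- runif(1, extent / 10, extent / 7)
      cx <- runif(1, radius + 2, extent - radius - 2)
      cy <- runif(1, radius + 2, extent - radius - 2)
      poly <- random_polygon(cx, cy, radius)
      inside <- point_in_polygon(xs - 0.5, ys - 0.5, poly)
      pix_mask <- matrix(inside, extent, extent)
      # keep a 2-pixel margin between segments
      near <- (xs - cx)^2 + (ys - cy)^2 <= (radius + 2)^2
      if (any(occupied & near)) next
      occupied <- occupied | near
      placed <- placed + 1L
      # one sign for all channels: segments differ in luminance as well
      # as in hue, as real labeled objects do
      sgn <- sample(c(-1, 1), 1L)
      seg_col <- base_col + sgn * (contrast + runif(3, 0, 0.1))
      seg_tex <- texture_field(extent, sigma = runif(1, 1, 4), sd = 0.03) +
        oriented_texture(extent, runif(1, 0, pi), runif(1, 4, 10), 0.12)
      for (ch in 1:3)
        px[, , ch][pix_mask] <- seg_col[ch] + seg_tex[pix_mask]
      grid_mask <- rasterize_polygon(poly, extent %/% stride,
                                     extent %/% stride, stride)
      masks[[placed]] <- segment_mask(grid_mask,
                                      label = paste0("segment_", placed))
    }
    structure(list(image = image_rgb(px, "raw"), masks = masks,
                   seed = seed,
                   params = list(n_segments = n_segments, extent = extent,
                                 contrast = contrast, stride = stride)),
              class = "scene_fixture")
  })
}

#' @export
print.scene_fixture <- function(x, ...) {
  cat(sprintf("<scene_fixture %dx%d px, %d segments, seed %d>\n",
              x$params$extent, x$params$extent, length(x$masks), x$seed))
  invisible(x)
}
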