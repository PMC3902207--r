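test_that("preprocessing resizes, centers and whitens", {
  img <- noise_image(1, 96)
  pre <- preprocess_image(img, target = c(300L, 400L))
  expect_identical(dim(pre)[1:2], c(300L, 400L))
  expect_identical(attr(pre, "stage"), "preprocessed")
  for (ch in 1:3) expect_lt(abs(mean(pre[, , ch])), 1e-6)

  # constant image: mean subtraction leaves zeros, filtering keeps them
  const <- image_rgb(array(0.7, c(64, 64, 3)), "raw")
  pre0 <- preprocess_image(const, target = c(32L, 32L))
  expect_true(all(abs(pre0) < 1e-12))

  # non-image input rejected
  expect_error(preprocess_image(matrix(1, 4, 4)), "image_rgb")
  expect_error(image_rgb(array(1, c(0, 4, 3))), "degenerate")
})

test_that("whitening of unit-variance white noise matches the eigenvalue oracle", {
  # white noise has identity covariance; with the +0.1 eigenvalue
  # regularizer every direction is scaled by 1/sqrt(1.1), so the output
  # variance is 1/1.1 of the input variance. The kernel needs a proper
  # corpus: estimating a patch covariance from a single image leaves
  # sampling noise in the eigenvalues that distorts the scale.
  kern_imgs <- lapply(1:8, function(i) noise_image(300 + i, 96))
  kern <- build_zca_kernel(kern_imgs, patch_extent = 6L)
  img <- noise_image(999, 96)
  px <- unclass(img)
  for (ch in 1:3) px[, , ch] <- px[, , ch] - mean(px[, , ch])
  v_in <- var(as.numeric(px))
  pre <- preprocess_image(img, target = c(96L, 96L), kernel = kern)
  v_out <- var(as.numeric(unclass(pre)))
  expect_equal(v_out / v_in, 1 / 1.1, tolerance = 0.05)
})

test_that("zca kernel on identity covariance is a scaled impulse", {
  imgs <- lapply(1:3, function(i) noise_image(100 + i, 80))
  kern <- build_zca_kernel(imgs, patch_extent = 8L)
  center <- c(5L, 5L)  # floor(8/2) + 1 in both dims
  expect_equal(kern[center[1], center[2]], 1 / sqrt(1.1),
               tolerance = 0.02)
  off <- kern
  off[center[1], center[2]] <- 0
  expect_lt(max(abs(off)), 0.05)
})

test_that("zca kernel is center-surround on correlated noise and decorrelates it", {
  mk_corr_image <- function(seed) {
    phasebind:::with_seed(seed, {
      m <- matrix(rnorm(96 * 96), 96)
      sm <- phasebind:::gauss_smooth(m, 2) * 5
      image_rgb(array(rep(sm, 3), c(96, 96, 3)), "raw")
    })
  }
  imgs <- lapply(1:3, mk_corr_image)
  kern <- build_zca_kernel(imgs, patch_extent = 8L)
  ctr <- kern[5, 5]
  expect_gt(ctr, 0)
  expect_lt(kern[4, 5], 0)
  expect_lt(kern[6, 5], 0)
  expect_lt(kern[5, 4], 0)
  expect_lt(kern[5, 6], 0)

  lag1 <- function(m) cor(as.numeric(m[, -1]), as.numeric(m[, -ncol(m)]))
  raw <- imgs[[1]][, , 1] - mean(imgs[[1]][, , 1])
  wh <- phasebind:::apply_kernel(unclass(imgs[[1]]), kern)[, , 1]
  expect_lt(abs(lag1(wh)), abs(lag1(raw)))
})

test_that("artificial stimuli have the stated geometry", {
  bars <- make_artificial_stimulus("collinear_bars", 128)
  # exactly two disjoint collinear foreground runs on the bar row
  fg_rows <- which(apply(bars[, , 1] < 0.5, 1, any))
  row <- bars[fg_rows[1], , 1] < 0.5
  runs <- rle(row)
  expect_identical(sum(runs$values), 2L)
  # both runs on the same rows: collinear
  for (r in fg_rows) expect_identical(bars[r, , 1], bars[fg_rows[1], , 1])

  circ <- make_artificial_stimulus("dashed_circle", 128)
  fg <- which(circ[, , 1] < 0.5, arr.ind = TRUE)
  ctr <- (128 + 1) / 2
  rad <- sqrt((fg[, 1] - ctr)^2 + (fg[, 2] - ctr)^2)
  expect_gt(min(rad), 128 / 3 - 4)
  expect_lt(max(rad), 128 / 3 + 4)

  unif <- make_artificial_stimulus("uniform", 64)
  expect_identical(length(unique(as.numeric(unif))), 1L)

  expect_error(make_artificial_stimulus("squares"))
})

test_that("synthetic scenes are deterministic, disjoint and contrasted", {
  s1 <- make_synthetic_scene(11, n_segments = 3, extent = 128)
  s2 <- make_synthetic_scene(11, n_segments = 3, extent = 128)
  expect_identical(unclass(s1$image), unclass(s2$image))
  expect_identical(lapply(s1$masks, `[[`, "mask"),
                   lapply(s2$masks, `[[`, "mask"))

  expect_length(s1$masks, 3L)
  overlap <- s1$masks[[1]]$mask & s1$masks[[2]]$mask |
    s1$masks[[1]]$mask & s1$masks[[3]]$mask |
    s1$masks[[2]]$mask & s1$masks[[3]]$mask
  expect_false(any(overlap))

  # per-channel mean color difference of each segment vs background
  seg_union <- Reduce(`|`, lapply(s1$masks, `[[`, "mask"))
  px_mask <- apply(seg_union, c(1, 2), identity)
  up <- px_mask[rep(seq_len(64), each = 2), rep(seq_len(64), each = 2)]
  for (m in s1$masks) {
    upm <- m$mask[rep(seq_len(64), each = 2), rep(seq_len(64), each = 2)]
    for (ch in 1:3) {
      segm <- mean(s1$image[, , ch][upm])
      bgm <- mean(s1$image[, , ch][!up])
      expect_gt(abs(segm - bgm), 0.25 - 0.06)
    }
  }
})

test_that("scene masks always pass the evaluation size filter", {
  for (seed in c(3, 17, 92)) {
    sc <- make_synthetic_scene(seed, n_segments = 3, extent = 128)
    expect_length(filter_masks(sc$masks), 3L)
  }
})

test_that("mask rasterization and filtering follow the grid conventions", {
  # axis-aligned rectangle of 5 x 4 grid cells at stride 2: pixel rect
  # from (10, 6) to (20, 14) covers grid cells 6..10 x 4..7
  poly <- cbind(x = c(10, 20, 20, 10), y = c(6, 6, 14, 14))
  m <- phasebind:::rasterize_polygon(poly, 20L, 20L, 2L)
  expect_identical(sum(m), 5L * 4L)

  mk <- function(area) segment_mask(matrix(rep(c(TRUE, FALSE),
    c(area, 40000 - area)), 200), "m")
  expect_length(filter_masks(list(mk(35))), 0L)
  expect_length(filter_masks(list(mk(36))), 1L)
  expect_length(filter_masks(list(mk(15000))), 1L)
  expect_length(filter_masks(list(mk(15001))), 0L)

  # idempotence
  masks <- list(mk(36), mk(35), mk(200))
  once <- filter_masks(masks)
  expect_identical(filter_masks(once), once)
})

test_that("labeled rasters and LabelMe XML load onto the neuron grid", {
  lab <- matrix(0L, 40, 40)
  lab[11:20, 11:30] <- 1L   # 10x20 px -> 5x10 grid cells
  lab[31:36, 5:10] <- 2L
  masks <- load_masks(lab, stride = 2L, labels = c("house", "car"))
  expect_length(masks, 2L)
  expect_identical(masks[[1]]$area, 50L)
  expect_identical(masks[[1]]$label, "house")

  xml <- paste0(
    "<annotation><imagesize><nrows>300</nrows><ncols>400</ncols>",
    "</imagesize><object><name>tree</name><polygon>",
    "<pt><x>40</x><y>40</y></pt><pt><x>120</x><y>40</y></pt>",
    "<pt><x>120</x><y>120</y></pt><pt><x>40</x><y>120</y></pt>",
    "</polygon></object></annotation>")
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  masks <- load_masks(path, stride = 2L, target = c(300L, 400L))
  expect_length(masks, 1L)
  expect_identical(masks[[1]]$label, "tree")
  # 80x80 px square -> 40x40 neuron cells
  expect_identical(masks[[1]]$area, 40L * 40L)
})

test_that("preprocessing is linear after mean subtraction", {
  img <- noise_image(5, 64)
  px <- unclass(img)
  for (ch in 1:3) px[, , ch] <- px[, , ch] - mean(px[, , ch])
  kern <- build_zca_kernel(list(image_rgb(px, "raw")), patch_extent = 8L)
  p1 <- preprocess_image(image_rgb(px, "raw"), target = c(64L, 64L),
                         kernel = kern)
  p2 <- preprocess_image(image_rgb(2.5 * px, "raw"), target = c(64L, 64L),
                         kernel = kern)
  expect_equal(unclass(p2), 2.5 * unclass(p1), tolerance = 1e-10)
})
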