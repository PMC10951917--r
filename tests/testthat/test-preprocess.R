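# Ground-truth preparation: normalization, denoising, instance segmentation
# and state classification.

test_that("per-slice normalization rescales linearly and projects per-pixel maxima", {
  sl <- matrix(c(10, 15, 20, 12), 2, 2)
  stack <- array(c(sl, sl * 0 + 5), c(2, 2, 2))
  expect_warning(np <- normalize_and_project(stack), "flat")
  expect_equal(np$normalized[, , 1], (sl - 10) / 10 * 255)
  expect_equal(np$normalized[1, 2, 1], 255)
  expect_equal(np$normalized[2, 1, 1], 127.5)
  expect_true(all(np$normalized[, , 2] == 0))
  # single-slice stack: projection equals the normalized slice
  np1 <- normalize_and_project(array(sl, c(2, 2, 1)))
  expect_equal(np1$max_image, np1$normalized[, , 1])
  # 3-slice stack against a per-pixel loop oracle
  st3 <- vs$with_seed(1, array(stats::runif(4 * 4 * 3), c(4, 4, 3)))
  np3 <- normalize_and_project(st3)
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) oracle[i, j] <- max(np3$normalized[i, j, ])
  expect_equal(np3$max_image, oracle)
  # idempotence: a full-range 8-bit image is unchanged
  full <- matrix(seq(0, 255, length.out = 16), 4, 4)
  expect_equal(normalize_and_project(array(full, c(4, 4, 1)))$max_image, full)
})

test_that("constant images are fixed points of enhancement and salt noise is removed", {
  cst <- matrix(127, 64, 64)
  expect_equal(enhance_and_denoise(cst), cst)
  # iterated median eliminates a single bright pixel entirely
  sp <- matrix(0, 64, 64)
  sp[30, 30] <- 255
  out <- enhance_and_denoise(sp, gauss_times = 0L)
  expect_equal(max(out) - min(out), 0)
  # the full pipeline attenuates it to a small residual bump
  full <- enhance_and_denoise(sp)
  expect_lt(max(full) - min(full), 0.1 * 255)
})

test_that("iterated Gaussian smoothing reconnects fragments of one nucleus", {
  X <- matrix(seq_len(64), 64, 64)
  Y <- t(X)
  fr <- matrix(0, 64, 64)
  fr[sqrt((X - 30)^2 + (Y - 30)^2) <= 2] <- 255
  fr[sqrt((X - 30)^2 + (Y - 36)^2) <= 2] <- 255   # 3 px gap between rims
  expect_identical(n_components(fr > 127), 2L)
  den <- enhance_and_denoise(fr, median_times = 2L)
  thr <- EBImage::otsu(EBImage::Image(den / 255), range = c(0, 1)) * 255
  expect_identical(n_components(den > thr), 1L)
})

test_that("watershed instance segmentation splits touching discs and tiles the foreground", {
  one <- disc_image(centers = list(c(50, 64)))
  seg1 <- segment_instances(one)
  expect_identical(max(seg1$labels), 1L)
  # two overlapping discs, centers 1.5 radii apart
  two <- disc_image(centers = list(c(50, 64), c(80, 64)))
  seg2 <- segment_instances(two)
  expect_identical(max(seg2$labels), 2L)
  # every foreground pixel gets exactly one label; labels never leave the
  # Otsu foreground
  thr <- EBImage::otsu(EBImage::Image(two / 255), range = c(0, 1)) * 255
  expect_identical(seg2$labels > 0L, two > thr)
  # a watershed line separates the two instances (both labels touch the
  # vertical through the overlap)
  expect_setequal(unique(as.vector(seg2$labels[seg2$labels > 0])), 1:2)
  # empty image: empty instance map, not an error
  expect_identical(max(segment_instances(matrix(0, 32, 32))$labels), 0L)
})

test_that("Otsu threshold of a bimodal image falls between the modes", {
  bi <- matrix(c(rep(50, 2048), rep(200, 2048)), 64, 64)
  thr <- EBImage::otsu(EBImage::Image(bi / 255), range = c(0, 1)) * 255
  expect_gt(thr, 50)
  expect_lt(thr, 200)
  # 1-D exhaustive variant used for state splitting behaves identically
  expect_gt(otsu_split(as.vector(bi)), 50)
  expect_lt(otsu_split(as.vector(bi)), 200)
})

test_that("state classification splits instance standard deviations by 1-D Otsu", {
  # four instances with designed sds {3, 4, 20, 22}
  lab <- matrix(0L, 20, 20)
  img <- matrix(0, 20, 20)
  sds <- c(3, 4, 20, 22)
  corners <- list(c(1, 1), c(1, 11), c(11, 1), c(11, 11))
  for (k in 1:4) {
    rr <- corners[[k]][1]:(corners[[k]][1] + 8)
    cc <- corners[[k]][2]:(corners[[k]][2] + 8)
    lab[rr, cc] <- k
    img[rr, cc] <- vs$with_seed(k, scale(stats::rnorm(81))) * sds[k] + 100
  }
  inst <- classify_states(vs$new_instances(lab), img)
  expect_identical(unname(inst$states), c("healthy", "healthy", "apoptotic", "apoptotic"))
  # the split agrees with an exhaustive between-class-variance scan
  expect_gt(otsu_split(sds), 4)
  expect_lt(otsu_split(sds), 20)
  # manual override replicates the revision step
  inst2 <- classify_states(vs$new_instances(lab), img,
                           overrides = c("1" = "apoptotic"))
  expect_identical(unname(inst2$states[1]), "apoptotic")
  expect_error(classify_states(vs$new_instances(lab), img,
                               overrides = c("9" = "healthy")), "not present")
})

test_that("degenerate classification inputs fall back to healthy with a warning", {
  lab1 <- matrix(1L, 6, 6)
  expect_warning(i1 <- classify_states(vs$new_instances(lab1), matrix(5, 6, 6)),
                 "single instance")
  expect_identical(unname(i1$states), "healthy")
  lab2 <- matrix(rep(1:2, each = 18), 6, 6)
  expect_warning(i2 <- classify_states(vs$new_instances(lab2), matrix(7, 6, 6)),
                 "identical")
  expect_identical(unname(i2$states), c("healthy", "healthy"))
})

test_that("training samples split the center slice into disjoint state channels", {
  lab <- matrix(0L, 8, 8)
  lab[2:4, 2:4] <- 1L
  lab[5:7, 5:7] <- 2L
  states <- c("1" = "healthy", "2" = "apoptotic")
  center <- matrix(100, 8, 8)
  bf <- vs$with_seed(3, array(stats::runif(8 * 8 * 2, 10, 20), c(8, 8, 2)))
  ts <- build_training_sample(center, vs$new_instances(lab, states), bf)
  # supports are disjoint and reconstruct the masked center slice
  expect_false(any(ts$target[, , 1] > 0 & ts$target[, , 2] > 0))
  expect_equal((ts$target[, , 1] + ts$target[, , 2]) * 255,
               center * (lab > 0), tolerance = 1e-12)
  expect_identical(ts$class_mask, lab)
  expect_true(all(ts$bright_field >= 0 & ts$bright_field <= 1))
  # all-healthy scene leaves channel 2 identically zero
  states_h <- c("1" = "healthy", "2" = "healthy")
  ts2 <- build_training_sample(center, vs$new_instances(lab, states_h), bf)
  expect_true(all(ts2$target[, , 2] == 0))
  expect_error(build_training_sample(center, vs$new_instances(lab), bf), "states")
})

test_that("resize honors the shape contract", {
  img <- vs$with_seed(4, matrix(stats::runif(64 * 48), 64, 48))
  expect_identical(dim(resize_image(img, 32L, 24L)), c(32L, 24L))
})
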