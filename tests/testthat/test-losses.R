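# Losses and metrics: closed forms, elementwise oracles, the mask-weight
# schedule, and decomposition of the total generator loss.

test_that("adversarial losses match closed forms and an elementwise oracle", {
  z0 <- matrix(0, 4, 4)
  l <- adversarial_losses(z0, z0)
  expect_equal(l$loss_D, -2 * log(0.5), tolerance = 1e-12)
  expect_equal(l$loss_G_adv, -log(0.5), tolerance = 1e-12)
  # saturated optimum: confident real/fake logits drive loss_D to ~0
  lsat <- adversarial_losses(matrix(40, 2, 2), matrix(-40, 2, 2))
  expect_lt(lsat$loss_D, 1e-6)
  # random maps against a scalar sigmoid/BCE oracle
  vs$with_seed(1, {
    r <- matrix(stats::rnorm(16), 4, 4)
    f <- matrix(stats::rnorm(16), 4, 4)
  })
  sig <- function(z) 1 / (1 + exp(-z))
  l2 <- adversarial_losses(r, f)
  expect_equal(l2$loss_D, mean(-log(sig(r))) + mean(-log(1 - sig(f))),
               tolerance = 1e-10)
  expect_equal(l2$loss_G_adv, mean(-log(sig(f))), tolerance = 1e-10)
})

test_that("SSIM is 1 at identity, symmetric, and handles constant images", {
  x <- vs$with_seed(2, matrix(stats::runif(24 * 24), 24, 24))
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  y <- vs$with_seed(3, matrix(stats::runif(24 * 24), 24, 24))
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  # constant vs equal constant
  a <- matrix(0.4, 16, 16)
  expect_equal(ssim(a, a), 1, tolerance = 1e-12)
  # constant vs different constant: variance terms vanish, the luminance
  # term governs the score
  b <- matrix(0.9, 16, 16)
  c1 <- (0.01)^2; c2 <- (0.03)^2
  lum <- (2 * 0.4 * 0.9 + c1) / (0.4^2 + 0.9^2 + c1)
  expect_equal(ssim(a, b), lum, tolerance = 1e-10)
})

test_that("full-image uniform window reproduces global-statistics SSIM", {
  r <- seq(0, 1, length.out = 16)
  x <- outer(r, r, `+`) / 2
  y <- outer(r, rev(r), `+`) / 2
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  c1 <- (0.01)^2; c2 <- (0.03)^2
  glob <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  expect_equal(ssim(x, y, window = 16L, gaussian = FALSE), glob, tolerance = 1e-10)
})

test_that("conventional loss composes L1 and SSIM distance and vanishes only at equality", {
  x <- vs$with_seed(4, array(stats::runif(8 * 8 * 2), c(8, 8, 2)))
  y <- vs$with_seed(5, array(stats::runif(8 * 8 * 2), c(8, 8, 2)))
  expect_equal(conventional_loss(x, x), 0, tolerance = 1e-12)
  cfg1 <- loss_config(alpha = 1)
  expect_equal(conventional_loss(x, y, cfg1), mean(abs(x - y)), tolerance = 1e-12)
  cfg <- loss_config(alpha = 0.5)
  expected <- 0.5 * mean(abs(x - y)) +
    0.5 * (1 - ssim(x, y, window = cfg$ssim_window, sigma = cfg$ssim_sigma))
  expect_equal(conventional_loss(x, y, cfg), expected, tolerance = 1e-12)
  expect_gt(conventional_loss(x, y, cfg), 0)
})

test_that("mask cross-entropy matches closed forms and an elementwise oracle", {
  lab <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  perfect <- array(0, c(2, 2, 3))
  for (i in 1:2) for (j in 1:2)
    perfect[i, j, ifelse(lab[i, j] == 0L, 3L, lab[i, j])] <- 1
  expect_equal(mask_loss(perfect, lab), 0, tolerance = 1e-9)
  uniform <- array(1 / 3, c(2, 2, 3))
  expect_equal(mask_loss(uniform, lab), log(3), tolerance = 1e-12)
  vs$with_seed(6, {
    raw <- array(stats::runif(4 * 4 * 3), c(4, 4, 3))
    labs <- matrix(sample(0:2, 16, TRUE), 4, 4)
  })
  m <- raw / array(rep(apply(raw, c(1, 2), sum), 3), dim(raw))
  oracle <- 0
  for (i in 1:4) for (j in 1:4)
    oracle <- oracle - log(m[i, j, ifelse(labs[i, j] == 0L, 3L, labs[i, j])]) / 16
  expect_equal(mask_loss(m, labs), oracle, tolerance = 1e-10)
  expect_error(mask_loss(m, matrix(3L, 4, 4)), "labels")
})

test_that("the mask-weight schedule steps down by 10% per period with a floor", {
  expect_identical(mask_weight(0), 250)
  expect_identical(mask_weight(1499), 250)
  expect_equal(mask_weight(1500), 225)
  expect_equal(mask_weight(3000), 250 * 0.81)
  expect_equal(mask_weight(1e6), 2.5)
  # non-increasing, bounded below (property over a wide epoch sweep)
  w <- mask_weight(seq(0, 1e6, by = 777), loss_config())
  expect_true(all(diff(w) <= 0))
  expect_true(all(w >= 2.5))
})

test_that("total generator loss is linear in its components with the stated weights", {
  expect_equal(total_generator_loss(0, 0, 0, 0), 0)
  expect_equal(total_generator_loss(1, 1, 1, 0), 1 + 100 + 250)
  expect_equal(total_generator_loss(0, 0, 1, 3000), 202.5)
  cfg <- loss_config()
  base <- total_generator_loss(0.3, 0.2, 0.1, 0)
  expect_equal(total_generator_loss(0.3 + 1, 0.2, 0.1, 0) - base, 1)
  expect_equal(total_generator_loss(0.3, 0.2 + 1, 0.1, 0) - base, cfg$lambda_conv)
  expect_equal(total_generator_loss(0.3, 0.2, 0.1 + 1, 0) - base, mask_weight(0, cfg))
})

test_that("MAE/SSIM/PSNR metrics match scalar oracles and the identity case", {
  x <- vs$with_seed(7, matrix(stats::runif(32 * 32), 32, 32))
  m0 <- metrics(x, x)
  expect_equal(m0$mae, 0)
  expect_equal(m0$ssim, 1, tolerance = 1e-12)
  expect_identical(m0$psnr, Inf)
  m1 <- metrics(pmin(x, 0.9) + 0.1, pmin(x, 0.9))
  expect_equal(m1$mae, 0.1, tolerance = 1e-12)
  expect_equal(m1$psnr, 20, tolerance = 1e-10)
  y <- vs$with_seed(8, matrix(stats::runif(32 * 32), 32, 32))
  m2 <- metrics(x, y)
  expect_equal(m2$mae, mean(abs(x - y)), tolerance = 1e-12)
  expect_equal(m2$psnr, 10 * log10(1 / mean((x - y)^2)), tolerance = 1e-12)
})
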