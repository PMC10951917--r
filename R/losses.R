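# Training objectives and evaluation metrics.
#
# The adversarial objective is the standard conditional-GAN binary
# cross-entropy minimax with the non-saturating generator loss. The
# "conventional" image loss is a convex combination of L1 distance and SSIM
# distance (1 - SSIM); the mask loss is per-pixel cross-entropy whose weight
# follows a stepped decay schedule (initial 250, x0.9 every 1500 epochs,
# floor 2.5). Evaluation metrics are MAE, SSIM and PSNR.

#' Loss configuration
#'
#' @param lambda_conv weight of the conventional (L1 + SSIM) loss relative
#'   to the adversarial loss
#' @param alpha weight in \[0,1\] balancing L1 (alpha) against SSIM distance
#'   (1 - alpha)
#' @param schedule list with `initial`, `decay`, `period_epochs`, `floor`
#'   governing the mask-loss weight
#' @param k1,k2 SSIM stabilization constants relative to the dynamic range
#' @param dynamic_range image dynamic range L used by SSIM and PSNR
#' @param ssim_window,ssim_sigma SSIM window size and Gaussian sigma
#' @return a `vs_loss_config` list
#' @export
loss_config <- function(lambda_conv = 100, alpha = 0.5,
                        schedule = list(initial = 250, decay = 0.9,
                                        period_epochs = 1500, floor = 2.5),
                        k1 = 0.01, k2 = 0.03, dynamic_range = 1,
                        ssim_window = 11L, ssim_sigma = 1.5) {
  stopifnot(schedule$initial > schedule$floor, schedule$floor > 0,
            schedule$decay > 0, schedule$decay < 1,
            alpha >= 0, alpha <= 1, lambda_conv > 0)
  structure(list(lambda_conv = lambda_conv, alpha = alpha, schedule = schedule,
                 k1 = k1, k2 = k2, dynamic_range = dynamic_range,
                 ssim_window = as.integer(ssim_window), ssim_sigma = ssim_sigma),
            class = "vs_loss_config")
}

# stable elementwise binary cross-entropy with logits
bce_logits <- function(z, target) {
  mean(pmax(z, 0) - target * z + log1p(exp(-abs(z))))
}

#' Adversarial losses from patch score maps
#'
#' `loss_D` is the discriminator's binary cross-entropy for labeling real
#' pairs 1 and generated pairs 0, averaged over patches; `loss_G_adv` is the
#' non-saturating generator term `-log sigmoid(fake)`.
#'
#' @param real_scores,fake_scores patch logit maps from [discriminate()]
#' @return list with `loss_D` and `loss_G_adv`
#' @export
adversarial_losses <- function(real_scores, fake_scores) {
  list(loss_D = bce_logits(real_scores, 1) + bce_logits(fake_scores, 0),
       loss_G_adv = bce_logits(fake_scores, 1))
}

# node version: mean BCE-with-logits of a score map against a 0/1 target
ad_bce <- function(scores, target) {
  z <- scores$val
  n <- length(z)
  val <- mean(pmax(z, 0) - target * z + log1p(exp(-abs(z))))
  sig <- 1 / (1 + exp(-z))
  ad_node(val, function(g) ad_acc(scores, g * (sig - target) / n))
}

gaussian_kernel <- function(size, sigma) {
  r <- (size - 1) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

uniform_kernel <- function(size) matrix(1 / size^2, size, size)

# SSIM graph on nodes (y is a constant); returns a scalar node
ad_ssim <- function(x, y_const, config) {
  d <- dim(x$val)
  win <- min(config$ssim_window, d[1], d[2])
  k <- gaussian_kernel(win, config$ssim_sigma)
  L <- config$dynamic_range
  c1 <- (config$k1 * L)^2
  c2 <- (config$k2 * L)^2
  y <- ad_const(y_const)
  mx <- ad_dwcorr(x, k); my <- ad_dwcorr(y, k)
  mxx <- ad_dwcorr(ad_mul(x, x), k)
  myy <- ad_dwcorr(ad_mul(y, y), k)
  mxy <- ad_dwcorr(ad_mul(x, y), k)
  vx <- ad_sub(mxx, ad_mul(mx, mx))
  vy <- ad_sub(myy, ad_mul(my, my))
  cxy <- ad_sub(mxy, ad_mul(mx, my))
  num <- ad_mul(ad_cadd(ad_cmul(ad_mul(mx, my), 2), c1),
                ad_cadd(ad_cmul(cxy, 2), c2))
  den <- ad_mul(ad_cadd(ad_add(ad_mul(mx, mx), ad_mul(my, my)), c1),
                ad_cadd(ad_add(vx, vy), c2))
  ad_mean(ad_div(num, den))
}

#' Structural similarity index
#'
#' Windowed SSIM with a Gaussian (default 11x11, sigma 1.5) or uniform
#' window, computed on the valid interior and averaged over windows and
#' channels. Symmetric in its two arguments; equals 1 iff the images are
#' identical.
#'
#' @param x,y numeric arrays or matrices of identical shape
#' @param dynamic_range intensity range L of the inputs
#' @param window window size (clamped to the image size)
#' @param sigma Gaussian window sigma
#' @param gaussian use a Gaussian window? (`FALSE` gives a uniform window,
#'   so a full-image window reproduces global mean/variance statistics)
#' @param k1,k2 stabilization constants
#' @return SSIM value in \[0, 1\] for non-negatively correlated images
#' @export
ssim <- function(x, y, dynamic_range = 1, window = 11L, sigma = 1.5,
                 gaussian = TRUE, k1 = 0.01, k2 = 0.03) {
  if (!all(dim(x) == dim(y)) || length(x) != length(y))
    stop("x and y must have identical shape")
  if (is.null(dim(x))) { x <- as.matrix(x); y <- as.matrix(y) }
  if (length(dim(x)) == 2L) { dim(x) <- c(dim(x), 1L); dim(y) <- c(dim(y), 1L) }
  d <- dim(x)
  win <- min(window, d[1], d[2])
  k <- if (gaussian) gaussian_kernel(win, sigma) else uniform_kernel(win)
  c1 <- (k1 * dynamic_range)^2
  c2 <- (k2 * dynamic_range)^2
  f <- function(z) vs_dwcorr_valid(z, d[1], d[2], d[3], k)
  mx <- f(x); my <- f(y)
  vx <- f(x * x) - mx^2
  vy <- f(y * y) - my^2
  cxy <- f(x * y) - mx * my
  mean(((2 * mx * my + c1) * (2 * cxy + c2)) /
       ((mx^2 + my^2 + c1) * (vx + vy + c2)))
}

#' Conventional image loss: alpha * L1 + (1 - alpha) * (1 - SSIM)
#'
#' @param image generated image array
#' @param target ground-truth array of the same shape
#' @param config a [loss_config()]
#' @return non-negative scalar; 0 iff `image == target`
#' @export
conventional_loss <- function(image, target, config = loss_config()) {
  if (!all(dim(image) == dim(target))) stop("image and target shapes differ")
  s <- ssim(image, target, dynamic_range = config$dynamic_range,
            window = config$ssim_window, sigma = config$ssim_sigma,
            k1 = config$k1, k2 = config$k2)
  config$alpha * mean(abs(image - target)) + (1 - config$alpha) * (1 - s)
}

ad_conventional_loss <- function(image, target, config) {
  l1 <- ad_mean_abs(ad_sub(image, ad_const(target)))
  dssim <- ad_cadd(ad_cmul(ad_ssim(image, target, config), -1), 1)
  ad_lincomb(list(l1, dssim), c(config$alpha, 1 - config$alpha))
}

#' Segmentation cross-entropy
#'
#' Mean per-pixel negative log-probability of the true class under the mask
#' probabilities. Labels: 0 = background, 1 = healthy, 2 = apoptotic
#' (probability channels 3, 1, 2 respectively).
#'
#' @param mask (H, W, 3) probability array with per-pixel channel sums 1
#' @param labels (H, W) integer matrix over \{0, 1, 2\}
#' @return non-negative scalar
#' @export
mask_loss <- function(mask, labels) {
  if (!all(labels %in% 0:2)) stop("labels must be in {0, 1, 2}")
  ch <- ifelse(labels == 0L, 3L, labels)
  n <- length(labels)
  idx <- cbind(rep(seq_len(nrow(labels)), ncol(labels)),
               rep(seq_len(ncol(labels)), each = nrow(labels)),
               as.vector(ch))
  p <- pmax(mask[idx], 1e-12)
  -mean(log(p))
}

# fused softmax + cross-entropy from mask logits (numerically stable)
ad_ce_from_logits <- function(logits, labels) {
  d <- dim(logits$val)
  n <- d[1] * d[2]
  Z <- matrix(logits$val, n, d[3])
  E <- exp(Z - rowmax(Z))
  P <- E / rowSums(E)
  ch <- as.vector(ifelse(labels == 0L, 3L, labels))
  sel <- cbind(seq_len(n), ch)
  val <- -mean(log(pmax(P[sel], 1e-12)))
  ad_node(val, function(g) {
    G <- P
    G[sel] <- G[sel] - 1
    ad_acc(logits, array(g * G / n, d))
  })
}

#' Dynamic mask-loss weight
#'
#' Stepped decay: `max(floor, initial * decay^floor(epoch / period))`.
#' Defaults give 250 at epoch 0, x0.9 every 1500 epochs, never below 2.5.
#'
#' @param epoch non-negative integer epoch index (0-based)
#' @param config a [loss_config()]
#' @return the weight applied to the mask cross-entropy at this epoch
#' @export
mask_weight <- function(epoch, config = loss_config()) {
  s <- config$schedule
  pmax(s$floor, s$initial * s$decay^(epoch %/% s$period_epochs))
}

#' Total generator loss
#'
#' `loss_G_adv + lambda_conv * conv + mask_weight(epoch) * mask`.
#'
#' @param loss_G_adv,conv,mask component losses
#' @param epoch epoch index for the mask-weight schedule
#' @param config a [loss_config()]
#' @return scalar total
#' @export
total_generator_loss <- function(loss_G_adv, conv, mask, epoch,
                                 config = loss_config()) {
  loss_G_adv + config$lambda_conv * conv + mask_weight(epoch, config) * mask
}

#' Image-quality metrics: MAE, SSIM, PSNR
#'
#' @param pred,target arrays of identical shape
#' @param dynamic_range intensity range L (PSNR = 10 log10(L^2 / MSE))
#' @param ... further arguments passed to [ssim()]
#' @return list with `mae`, `ssim`, `psnr` (Inf when MSE = 0)
#' @export
metrics <- function(pred, target, dynamic_range = 1, ...) {
  if (!all(dim(pred) == dim(target))) stop("pred and target shapes differ")
  mse <- mean((pred - target)^2)
  list(mae = mean(abs(pred - target)),
       ssim = ssim(pred, target, dynamic_range = dynamic_range, ...),
       psnr = if (mse == 0) Inf else 10 * log10(dynamic_range^2 / mse))
}
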