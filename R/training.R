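# Augmentation, alternating adversarial optimization, cross-validation fold
# rotation and checkpoint tracking.

#' Training configuration
#'
#' @param batch_size samples per optimizer step
#' @param epochs training epochs (the full-scale reference schedule is 4500;
#'   the default here is a desk-scale run)
#' @param adam_betas Adam (beta1, beta2)
#' @param lr_G,lr_D generator / discriminator learning rates (two-time-scale
#'   convention: the discriminator runs faster)
#' @param crop_size random-crop size; must divide by 32 and fit the scenes
#' @param fold_rotation_period epochs between train/validation fold
#'   rotations (the test fold is never touched)
#' @param sn_iter spectral-norm power iterations per forward pass
#' @param seed master seed for initialization, shuffling and augmentation
#' @return a `vs_train_config` list
#' @export
train_config <- function(batch_size = 8L, epochs = 50L,
                         adam_betas = c(0.5, 0.999), lr_G = 1e-4, lr_D = 4e-4,
                         crop_size = 128L, fold_rotation_period = 50L,
                         sn_iter = 1L, seed = 1L) {
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 adam_betas = adam_betas, lr_G = lr_G, lr_D = lr_D,
                 crop_size = as.integer(crop_size),
                 fold_rotation_period = as.integer(fold_rotation_period),
                 sn_iter = as.integer(sn_iter), seed = as.integer(seed)),
            class = "vs_train_config")
}

rot90a <- function(a, k) {
  k <- k %% 4L
  if (k == 0L) return(a)
  r1 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  f <- function(m) { for (i in seq_len(k)) m <- r1(m); m }
  if (length(dim(a)) == 2L) return(f(a))
  d <- dim(a)
  nd <- if (k %% 2L == 1L) c(d[2], d[1], d[3]) else d
  out <- array(a[1], nd)
  for (c in seq_len(d[3])) out[, , c] <- f(a[, , c])
  out
}

apply_geom <- function(a, flip_h, flip_v, rot, r0, c0, crop) {
  is2d <- length(dim(a)) == 2L
  if (is2d) dim(a) <- c(dim(a), 1L)
  if (flip_h) a <- a[dim(a)[1]:1, , , drop = FALSE]
  if (flip_v) a <- a[, dim(a)[2]:1, , drop = FALSE]
  a <- rot90a(a, rot)
  a <- a[r0 + seq_len(crop), c0 + seq_len(crop), , drop = FALSE]
  if (is2d) dim(a) <- dim(a)[1:2]
  a
}

#' Augment a training sample
#'
#' Applies an identical random flip / 90-degree rotation / crop to the
#' bright-field stack, the target channels and the class mask, so pixels and
#' their labels move together. Rotations are restricted to multiples of 90
#' degrees to avoid interpolating class labels.
#'
#' @param sample list with `bright_field`, `target`, `class_mask`
#' @param seed integer seed determining the transform
#' @param crop_size output spatial size
#' @return the transformed sample
#' @export
augment <- function(sample, seed, crop_size) {
  d <- dim(sample$bright_field)
  if (crop_size > min(d[1:2]))
    stop("crop_size exceeds the sample dimensions")
  with_seed(seed, {
    flip_h <- stats::runif(1) < 0.5
    flip_v <- stats::runif(1) < 0.5
    rot <- sample(0:3, 1L)
    dd <- if (rot %% 2L == 1L) d[c(2, 1)] else d[1:2]
    r0 <- sample(0:(dd[1] - crop_size), 1L)
    c0 <- sample(0:(dd[2] - crop_size), 1L)
    list(bright_field = apply_geom(sample$bright_field, flip_h, flip_v, rot, r0, c0, crop_size),
         target = apply_geom(sample$target, flip_h, flip_v, rot, r0, c0, crop_size),
         class_mask = apply_geom(sample$class_mask, flip_h, flip_v, rot, r0, c0, crop_size))
  })
}

scene_sample <- function(scene) {
  list(bright_field = scene$bright_field,
       target = scene$fluorescent_target,
       class_mask = scene$class_mask)
}

# deep copy of parameter values (checkpoint)
snapshot_params <- function(params) lapply(params, function(p) p$val)

restore_params <- function(params, snap) {
  for (i in seq_along(params)) params[[i]]$val <- snap[[i]]
  invisible(NULL)
}

concat_cond <- function(x, y) {
  dx <- dim(x); dy <- dim(y)
  array(c(x, y), c(dx[1], dx[2], dx[3] + dy[3]))
}

# fold rotation: circular shift of the validation block through the
# train+val pool; the test fold never moves
rotate_folds <- function(pool, n_val, rotation) {
  n <- length(pool)
  off <- (rotation * n_val) %% n
  val <- pool[(off + seq_len(n_val) - 1L) %% n + 1L]
  list(train = setdiff(pool, val), val = val)
}

#' Train the translation GAN
#'
#' Alternates a discriminator step (binary cross-entropy on real and
#' detached generated pairs) and a generator step (adversarial +
#' lambda * conventional + dynamically weighted mask cross-entropy) per
#' batch, with random flip/rotation/crop augmentation. Validation MAE/SSIM/
#' PSNR are logged each epoch and the best-validation-MAE parameter snapshot
#' is retained; train/validation folds rotate every
#' `fold_rotation_period` epochs.
#'
#' @param dataset a `vs_dataset` from [generate_dataset()] (or a list with
#'   `scenes` and `split`)
#' @param g_config a [generator_config()]
#' @param d_config a [discriminator_config()]; its `input_slices` and
#'   `image_channels` must match the generator
#' @param l_config a [loss_config()]
#' @param t_config a [train_config()]
#' @param verbose print per-epoch progress?
#' @return a `vs_fit`: list with `generator`, `discriminator`, `log`
#'   (per-epoch data frame), `best` (parameter snapshot + epoch), configs
#' @export
train <- function(dataset, g_config, d_config, l_config = loss_config(),
                  t_config = train_config(), verbose = FALSE) {
  img_ch <- if (g_config$variant == "single_1ch") 1L else 2L
  if (d_config$image_channels != img_ch)
    stop("d_config$image_channels must match the generator output channels")
  if (d_config$input_slices != g_config$input_slices)
    stop("d_config$input_slices must match g_config$input_slices")
  pool <- which(dataset$split != "test")
  if (!length(pool)) stop("empty train split")
  n_val <- max(1L, sum(dataset$split == "val"))
  dual <- g_config$variant == "dual"
  with_seed(t_config$seed, {
    g <- build_generator(g_config)
    d <- build_discriminator(d_config)
    opt_g <- new_adam(g$params, lr = t_config$lr_G, betas = t_config$adam_betas)
    opt_d <- new_adam(d$params, lr = t_config$lr_D, betas = t_config$adam_betas)
    log <- vector("list", t_config$epochs)
    best <- list(val_mae = Inf, epoch = NA_integer_, params = NULL)
    status <- "completed"
    sn_it <- t_config$sn_iter
    for (epoch in seq_len(t_config$epochs)) {
      rotation <- (epoch - 1L) %/% t_config$fold_rotation_period
      folds <- rotate_folds(pool, n_val, rotation)
      stopifnot(!any(folds$train %in% which(dataset$split == "test")),
                !any(folds$val %in% which(dataset$split == "test")))
      ord <- folds$train[sample.int(length(folds$train))]
      w_e <- mask_weight(epoch - 1L, l_config)
      ep <- c(d_loss = 0, g_adv = 0, conv = 0, mask = 0, n = 0)
      for (b0 in seq(1L, length(ord), by = t_config$batch_size)) {
        idx <- ord[b0:min(b0 + t_config$batch_size - 1L, length(ord))]
        nb <- length(idx)
        batch <- lapply(idx, function(i)
          augment(scene_sample(dataset$scenes[[i]]),
                  seed = t_config$seed + epoch * 10007L + i,
                  crop_size = t_config$crop_size))
        tgt_of <- function(s) {
          if (img_ch == 1L) {
            t1 <- pmax(s$target[, , 1], s$target[, , 2])
            array(t1, c(dim(t1), 1L))
          } else s$target
        }
        # --- discriminator step ---
        zero_grads(d$params)
        for (s in batch) {
          ad_begin(grad = FALSE)
          fake <- gen_fwd(g, ad_const(s$bright_field), sn_it)$translation$val
          ad_begin(grad = TRUE)
          rs <- disc_fwd(d, ad_const(concat_cond(s$bright_field, tgt_of(s))), sn_it)
          fs <- disc_fwd(d, ad_const(concat_cond(s$bright_field, fake)), sn_it)
          dl <- ad_lincomb(list(ad_bce(rs, 1), ad_bce(fs, 0)), c(1 / nb, 1 / nb))
          ad_backward(dl)
          ep["d_loss"] <- ep["d_loss"] + dl$val * nb
        }
        adam_step(opt_d)
        # --- generator step ---
        zero_grads(g$params)
        zero_grads(d$params)
        for (s in batch) {
          ad_begin(grad = TRUE)
          out <- gen_fwd(g, ad_const(s$bright_field), sn_it)
          fs <- disc_fwd(d, ad_concat_c(ad_const(s$bright_field), out$translation), sn_it)
          adv <- ad_bce(fs, 1)
          conv <- ad_conventional_loss(out$translation, tgt_of(s), l_config)
          if (dual) {
            mloss <- ad_ce_from_logits(out$mask_logits, s$class_mask)
            gl <- ad_lincomb(list(adv, conv, mloss),
                             c(1, l_config$lambda_conv, w_e) / nb)
            ep["mask"] <- ep["mask"] + mloss$val
          } else {
            gl <- ad_lincomb(list(adv, conv), c(1, l_config$lambda_conv) / nb)
          }
          ad_backward(gl)
          ep["g_adv"] <- ep["g_adv"] + adv$val
          ep["conv"] <- ep["conv"] + conv$val
        }
        adam_step(opt_g)
        zero_grads(d$params)
        ep["n"] <- ep["n"] + nb
      }
      # --- validation ---
      vm <- c(mae = 0, ssim = 0, psnr = 0)
      for (i in folds$val) {
        sc <- dataset$scenes[[i]]
        out <- generate(g, sc$bright_field, sn_iter = sn_it)
        tgt <- if (img_ch == 1L) {
          t1 <- pmax(sc$fluorescent_target[, , 1], sc$fluorescent_target[, , 2])
          array(t1, c(dim(t1), 1L))
        } else sc$fluorescent_target
        pred <- pmin(pmax(out$translation, 0), 1)
        mt <- metrics(pred, tgt, dynamic_range = 1)
        vm <- vm + c(mt$mae, mt$ssim, min(mt$psnr, 99))
      }
      vm <- vm / length(folds$val)
      n <- max(1, ep["n"])
      row <- data.frame(epoch = epoch, d_loss = ep["d_loss"] / n,
                        g_adv = ep["g_adv"] / n, conv = ep["conv"] / n,
                        mask = ep["mask"] / n, mask_weight = w_e,
                        val_mae = vm["mae"], val_ssim = vm["ssim"],
                        val_psnr = vm["psnr"], row.names = NULL)
      log[[epoch]] <- row
      if (!all(is.finite(unlist(row)))) {
        warning("non-finite loss at epoch ", epoch,
                "; aborting with last good checkpoint")
        status <- "diverged"
        break
      }
      if (vm["mae"] < best$val_mae) {
        best <- list(val_mae = vm["mae"], epoch = epoch,
                     params = snapshot_params(g$params))
      }
      if (verbose)
        message(sprintf("epoch %3d  D %.3f  adv %.3f  conv %.4f  mask %.4f (w=%.1f)  val MAE %.4f",
                        epoch, row$d_loss, row$g_adv, row$conv, row$mask, w_e,
                        row$val_mae))
    }
    structure(list(generator = g, discriminator = d,
                   log = do.call(rbind, log[!vapply(log, is.null, TRUE)]),
                   best = best, status = status,
                   g_config = g_config, d_config = d_config,
                   l_config = l_config, t_config = t_config),
              class = "vs_fit")
  })
}

#' Restore the best-validation checkpoint into a fit's generator
#' @param fit a `vs_fit`
#' @return the fit, with generator parameters set to the best snapshot
#' @export
use_best_checkpoint <- function(fit) {
  if (!is.null(fit$best$params)) restore_params(fit$generator$params, fit$best$params)
  fit
}

#' @export
print.vs_fit <- function(x, ...) {
  cat(sprintf("<vs_fit> %s, %d epoch(s); best val MAE %.4f at epoch %s\n",
              x$status, nrow(x$log), x$best$val_mae, x$best$epoch))
  invisible(x)
}
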