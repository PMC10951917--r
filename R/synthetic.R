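# Seeded synthetic microscopy scenes.
#
# Emulates the statistical structure the translation method assumes: paired
# bright-field z-stacks (13 slices, 0.3 um spacing, slice-dependent defocus
# blur) and single-plane fluorescent nuclei targets. Healthy nuclei are
# smooth-interior ellipses (low internal intensity variance); apoptotic
# nuclei are clusters of 3-8 small bright fragments inside an ellipse
# footprint (high internal variance, karyorrhexis-like). Cell bodies appear
# in bright-field as larger low-contrast rings around each nucleus; nuclei
# themselves are nearly invisible in bright-field apart from a faint
# state-dependent texture. Every scene is fully determined by its seed.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic scene configuration
#'
#' @param height,width scene size in pixels
#' @param n_healthy,n_apoptotic nucleus counts per state
#' @param n_slices bright-field slices S
#' @param slice_spacing_um axial slice spacing, micrometers
#' @param focus_slice index of the in-focus slice (default: middle)
#' @param defocus_sigma_per_um blur sigma gained per micrometer of defocus
#' @param noise_sd additive Gaussian noise sd on bright-field slices
#' @param fragment_count_range apoptotic fragment count range
#' @param touching_pair_prob probability a nucleus gets a touching partner
#' @param nucleus_radius_range semi-axis range in pixels
#' @param seed integer seed; fully determines the scene
#' @return a `vs_scene_config` list
#' @export
scene_config <- function(height = 256L, width = 256L, n_healthy = 8L,
                         n_apoptotic = 5L, n_slices = 13L,
                         slice_spacing_um = 0.3,
                         focus_slice = (n_slices + 1L) %/% 2L,
                         defocus_sigma_per_um = 1.2, noise_sd = 0.02,
                         fragment_count_range = c(3L, 8L),
                         touching_pair_prob = 0.15,
                         nucleus_radius_range = c(9, 14), seed = 1L) {
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_healthy = as.integer(n_healthy),
                 n_apoptotic = as.integer(n_apoptotic),
                 n_slices = as.integer(n_slices),
                 slice_spacing_um = slice_spacing_um,
                 focus_slice = as.integer(focus_slice),
                 defocus_sigma_per_um = defocus_sigma_per_um,
                 noise_sd = noise_sd,
                 fragment_count_range = as.integer(fragment_count_range),
                 touching_pair_prob = touching_pair_prob,
                 nucleus_radius_range = nucleus_radius_range,
                 seed = as.integer(seed)),
            class = "vs_scene_config")
}

ellipse_mask <- function(H, W, cx, cy, a, b, theta, scale = 1) {
  X <- matrix(seq_len(H), H, W)
  Y <- matrix(seq_len(W), H, W, byrow = TRUE)
  dx <- X - cx; dy <- Y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / (a * scale))^2 + (v / (b * scale))^2 <= 1
}

gauss_blob <- function(H, W, cx, cy, sigma) {
  X <- matrix(seq_len(H), H, W)
  Y <- matrix(seq_len(W), H, W, byrow = TRUE)
  exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sigma^2))
}

#' Generate one paired synthetic scene
#'
#' @param config a [scene_config()]
#' @return a `vs_scene`: list with `bright_field` (H, W, S) in \[0, 1\],
#'   `fluorescent_target` (H, W, 2) in \[0, 1\] (channel 1 healthy, channel 2
#'   apoptotic), `class_mask` (H, W) over \{0, 1, 2\}, `instances`
#'   (`vs_instances` with true states), `fluor_clean` (H, W) combined clean
#'   fluorescence, `config`, and `n_placed`
#' @export
generate_scene <- function(config = scene_config()) {
  with_seed(config$seed, {
    H <- config$height; W <- config$width
    rr <- config$nucleus_radius_range
    labels <- matrix(0L, H, W)
    states <- character(0)
    fluor <- array(0, c(H, W, 2L))
    bf_sig <- matrix(0, H, W)     # in-plane bright-field signature
    margin <- rr[2] + 2
    queue <- c(rep("healthy", config$n_healthy),
               rep("apoptotic", config$n_apoptotic))
    if (length(queue) > 1L) queue <- sample(queue)
    pending_partner <- NULL
    k <- 0L
    i <- 1L
    while (i <= length(queue)) {
      st <- queue[i]
      placed <- FALSE
      for (try in 1:60) {
        a <- stats::runif(1, rr[1], rr[2])
        b <- stats::runif(1, 0.7 * a, a)
        theta <- stats::runif(1, 0, pi)
        if (!is.null(pending_partner)) {
          ang <- stats::runif(1, 0, 2 * pi)
          dist <- (pending_partner$a + a) * stats::runif(1, 0.95, 1.1)
          cx <- pending_partner$cx + dist * cos(ang)
          cy <- pending_partner$cy + dist * sin(ang)
          if (cx < margin || cx > H - margin || cy < margin || cy > W - margin) next
        } else {
          cx <- stats::runif(1, margin, H - margin)
          cy <- stats::runif(1, margin, W - margin)
        }
        m <- ellipse_mask(H, W, cx, cy, a, b, theta)
        overlap <- sum(labels[m] > 0L) / max(1L, sum(m))
        lim <- if (is.null(pending_partner)) 0 else 0.08
        if (overlap > lim) next
        k <- k + 1L
        labels[m & labels == 0L] <- k
        states[k] <- st
        mk <- labels == k   # own pixels only, so state channels stay disjoint
        if (st == "healthy") {
          base <- stats::runif(1, 0.55, 0.7)
          grad <- gauss_blob(H, W, cx, cy, max(a, b))
          fl <- (base + 0.04 * (grad - 0.5)) * mk
          fluor[, , 1] <- pmax(fluor[, , 1], fl)
          bf_sig <- bf_sig - 0.13 * m * grad
        } else {
          nf <- sample(seq(config$fragment_count_range[1],
                           config$fragment_count_range[2]), 1L)
          fl <- 0.06 * m
          spk <- matrix(0, H, W)
          fcs <- matrix(NA_real_, 0, 2)
          for (f in 1:nf) {
            for (ft in 1:30) {
              ru <- sqrt(stats::runif(1)) * 0.75
              ang <- stats::runif(1, 0, 2 * pi)
              fx <- cx + ru * a * cos(theta) * cos(ang) - ru * b * sin(theta) * sin(ang)
              fy <- cy + ru * a * sin(theta) * cos(ang) + ru * b * cos(theta) * sin(ang)
              # keep >= 1 px gap between fragment cores so smoothing can
              # reconnect them into one component downstream
              if (nrow(fcs) == 0 ||
                  min(sqrt((fcs[, 1] - fx)^2 + (fcs[, 2] - fy)^2)) > 4.5) {
                fcs <- rbind(fcs, c(fx, fy))
                blob <- gauss_blob(H, W, fx, fy, stats::runif(1, 1.2, 1.8))
                fl <- fl + 0.95 * blob
                spk <- spk + blob
                break
              }
            }
          }
          fluor[, , 2] <- pmax(fluor[, , 2], pmin(fl, 1) * mk)
          bf_sig <- bf_sig + (0.22 * (spk - mean(spk[m])) - 0.03) * m
        }
        # low-contrast cell body ring, larger than the nucleus
        body <- ellipse_mask(H, W, cx, cy, a, b, theta, scale = stats::runif(1, 1.7, 2.1)) &
          !ellipse_mask(H, W, cx, cy, a, b, theta, scale = 1.35)
        bf_sig <- bf_sig + 0.08 * body
        placed <- TRUE
        break
      }
      # with some probability the next queued nucleus is placed touching
      # this one (counts are preserved; only the geometry changes)
      if (placed && is.null(pending_partner) &&
          stats::runif(1) < config$touching_pair_prob) {
        pending_partner <- list(cx = cx, cy = cy, a = a)
      } else {
        pending_partner <- NULL
      }
      i <- i + 1L
    }
    cm <- matrix(0L, H, W)
    if (k > 0L) {
      st_code <- ifelse(states == "healthy", 1L, 2L)
      cm[labels > 0L] <- st_code[labels[labels > 0L]]
    }
    bf <- array(0, c(H, W, config$n_slices))
    for (s in seq_len(config$n_slices)) {
      dz <- abs(s - config$focus_slice) * config$slice_spacing_um
      sl <- 0.5 + bf_sig
      sigma <- 0.4 + config$defocus_sigma_per_um * dz
      sl <- EBImage::gblur(sl, sigma = sigma)
      sl <- sl + stats::rnorm(H * W, sd = config$noise_sd)
      bf[, , s] <- pmin(pmax(sl, 0), 1)
    }
    st <- if (k > 0L) stats::setNames(states, as.character(seq_len(k))) else character(0)
    structure(list(bright_field = bf,
                   fluorescent_target = fluor,
                   class_mask = cm,
                   instances = new_instances(labels, st),
                   fluor_clean = pmax(fluor[, , 1], fluor[, , 2]),
                   config = config,
                   n_placed = k),
              class = "vs_scene")
  })
}

#' @export
print.vs_scene <- function(x, ...) {
  cat(sprintf("<vs_scene> %dx%d, %d slice(s), %d nuclei (%d healthy / %d apoptotic), seed %d\n",
              x$config$height, x$config$width, x$config$n_slices, x$n_placed,
              sum(x$instances$states == "healthy"),
              sum(x$instances$states == "apoptotic"), x$config$seed))
  invisible(x)
}

#' Emulate a raw fluorescent z-stack for a scene
#'
#' Produces an S-slice stack (default 24, 0.3 um spacing) of the scene's
#' clean fluorescence under slice-dependent defocus blur plus noise, for
#' exercising the ground-truth preparation pipeline.
#'
#' @param scene a `vs_scene`
#' @param n_slices number of fluorescent slices
#' @param noise_sd additive noise sd
#' @return numeric array (H, W, n_slices) of non-negative intensities
#' @export
generate_fluorescent_stack <- function(scene, n_slices = 24L, noise_sd = 0.01) {
  with_seed(scene$config$seed + 7919L, {
    H <- scene$config$height; W <- scene$config$width
    ctr <- (n_slices + 1) / 2
    out <- array(0, c(H, W, n_slices))
    for (s in seq_len(n_slices)) {
      dz <- abs(s - ctr) * scene$config$slice_spacing_um
      sl <- EBImage::gblur(scene$fluor_clean, sigma = 0.4 + 0.8 * dz)
      sl <- sl * (1 / (1 + 0.8 * dz)) + abs(stats::rnorm(H * W, sd = noise_sd))
      out[, , s] <- sl
    }
    out
  })
}

#' Generate a dataset of scenes with a train/validation/test split
#'
#' Scene seeds derive deterministically from the master seed; the split uses
#' the 66:12:8 proportions (rounded; sizes always sum to `n_scenes`) with the
#' test subset fixed.
#'
#' @param n_scenes number of scenes (>= 3)
#' @param config base [scene_config()]; its seed acts as the master seed
#' @return a `vs_dataset`: list with `scenes`, `split` (character vector
#'   "train"/"val"/"test"), `seeds`, `config`
#' @export
generate_dataset <- function(n_scenes, config = scene_config()) {
  if (n_scenes < 3L) stop("need at least 3 scenes for a 3-way split")
  seeds <- config$seed + 97L * seq_len(n_scenes)
  scenes <- lapply(seeds, function(s) {
    cf <- config; cf$seed <- s
    generate_scene(cf)
  })
  n_test <- max(1L, round(n_scenes * 8 / 86))
  n_val <- max(1L, round(n_scenes * 12 / 86))
  n_train <- n_scenes - n_test - n_val
  split <- with_seed(config$seed, {
    perm <- sample(n_scenes)
    sp <- character(n_scenes)
    sp[perm[seq_len(n_train)]] <- "train"
    sp[perm[n_train + seq_len(n_val)]] <- "val"
    sp[perm[n_train + n_val + seq_len(n_test)]] <- "test"
    sp
  })
  structure(list(scenes = scenes, split = split, seeds = seeds, config = config),
            class = "vs_dataset")
}

#' @export
print.vs_dataset <- function(x, ...) {
  cat(sprintf("<vs_dataset> %d scene(s): %d train / %d val / %d test\n",
              length(x$scenes), sum(x$split == "train"),
              sum(x$split == "val"), sum(x$split == "test")))
  invisible(x)
}
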