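# Ground-truth preparation pipeline: raw fluorescent z-stacks to 2-channel
# targets, 3-class masks, and per-nucleus health states.
#
# Steps: per-slice min-max normalization to 8-bit range and maximum-intensity
# projection; CLAHE (clip 2) + 4 passes of Gaussian smoothing (reconnecting
# karyorrhexis fragments of one nucleus) + 12 passes of median filtering;
# Otsu threshold; marker-controlled watershed on the distance transform to
# split touching nuclei; per-nucleus intensity standard deviation split by
# 1-D Otsu into healthy (smooth, low sd) vs apoptotic (fragmented, high sd);
# the center slice is masked per state group into the two target channels.

#' Per-slice min-max normalization and maximum projection
#'
#' Rescales each slice of a raw fluorescent z-stack to the 8-bit range
#' \[0, 255\] and takes the per-pixel maximum along z. A flat slice
#' (max == min) is mapped to zeros with a warning.
#'
#' @param stack numeric array (H, W, S) of non-negative intensities
#' @return list with `normalized` (H, W, S) and `max_image` (H, W)
#' @export
normalize_and_project <- function(stack) {
  if (length(dim(stack)) == 2L) dim(stack) <- c(dim(stack), 1L)
  d <- dim(stack)
  out <- stack
  for (s in seq_len(d[3])) {
    sl <- stack[, , s]
    rng <- range(sl)
    if (rng[2] > rng[1]) {
      out[, , s] <- (sl - rng[1]) / (rng[2] - rng[1]) * 255
    } else {
      warning(sprintf("flat slice %d mapped to zeros", s))
      out[, , s] <- 0
    }
  }
  mx <- out[, , 1]
  if (d[3] > 1L) for (s in 2:d[3]) mx <- pmax(mx, out[, , s])
  list(normalized = out, max_image = mx)
}

#' Contrast enhancement and iterated denoising
#'
#' CLAHE with clip limit 2, then `gauss_times` passes of Gaussian smoothing
#' (merging fragments of a single fragmented nucleus into one component) and
#' `median_times` passes of median filtering (removing salt-and-pepper
#' noise).
#'
#' @param img matrix with values in the 8-bit range \[0, 255\]
#' @param clip CLAHE contrast limiting value
#' @param tiles CLAHE tile grid size (tiles x tiles)
#' @param gauss_sigma,gauss_times Gaussian kernel sigma and pass count
#' @param median_size,median_times median kernel width (odd) and pass count
#' @return matrix in \[0, 255\]
#' @export
enhance_and_denoise <- function(img, clip = 2, tiles = 8L, gauss_sigma = 1,
                                gauss_times = 4L, median_size = 3L,
                                median_times = 12L) {
  x <- pmin(pmax(img / 255, 0), 1)
  if (stats::sd(x) > 0) {
    x <- EBImage::clahe(EBImage::Image(x), nx = tiles, ny = tiles, limit = clip)
    x <- EBImage::imageData(x)
  }
  for (i in seq_len(gauss_times)) x <- EBImage::gblur(x, sigma = gauss_sigma)
  x <- pmin(pmax(x, 0), 1)
  r <- (median_size - 1L) %/% 2L
  for (i in seq_len(median_times)) x <- EBImage::medianFilter(x, size = r)
  as.matrix(EBImage::imageData(x)) * 255
}

#' Split the Otsu foreground into labeled nucleus instances
#'
#' Thresholds the denoised image with Otsu's method, computes the distance
#' transform of the foreground, places markers at its local maxima (minimum
#' separation `min_sep`, discarding peaks below `peak_frac` of the maximum
#' distance) and floods the inverted distance map from the markers
#' (marker-controlled watershed). Every foreground pixel receives exactly
#' one label.
#'
#' @param img denoised matrix in \[0, 255\]
#' @param min_sep minimum separation between markers, pixels
#' @param peak_frac discard distance-map peaks below this fraction of the
#'   global maximum
#' @return a `vs_instances` object: list with integer `labels` matrix
#'   (0 = background, instances 1..K) and `states` (NULL until
#'   [classify_states()])
#' @export
segment_instances <- function(img, min_sep = 7L, peak_frac = 0.3) {
  x <- pmin(pmax(img / 255, 0), 1)
  lab <- matrix(0L, nrow(x), ncol(x))
  if (stats::sd(x) == 0) return(new_instances(lab))
  thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  fg <- x > thr
  if (!any(fg)) return(new_instances(lab))
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(fg)))
  r <- max(1L, min_sep %/% 2L)
  mx <- EBImage::imageData(EBImage::dilate(dm, EBImage::makeBrush(2L * r + 1L, "disc")))
  peaks <- fg & (dm >= mx - 1e-9) & (dm >= peak_frac * max(dm))
  seeds <- EBImage::bwlabel(EBImage::Image(peaks))
  if (max(seeds) == 0L) seeds <- EBImage::bwlabel(EBImage::Image(fg))
  ws <- EBImage::propagate(EBImage::Image(-dm), seeds = seeds,
                           mask = EBImage::Image(fg))
  lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(x), ncol(x))
  # relabel contiguously 1..K
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  lab <- matrix(match(lab, ids, nomatch = 0L), nrow(lab), ncol(lab))
  storage.mode(lab) <- "integer"
  new_instances(lab)
}

new_instances <- function(labels, states = NULL) {
  structure(list(labels = labels, states = states), class = "vs_instances")
}

#' @export
print.vs_instances <- function(x, ...) {
  k <- max(x$labels)
  cat(sprintf("<vs_instances> %d instance(s)%s\n", k,
              if (is.null(x$states)) " (states unset)"
              else sprintf(": %d healthy / %d apoptotic",
                           sum(x$states == "healthy"),
                           sum(x$states == "apoptotic"))))
  invisible(x)
}

#' 1-D Otsu split of a numeric vector
#'
#' Exhaustive scan over midpoints between sorted unique values, maximizing
#' the between-class variance.
#'
#' @param v numeric vector
#' @return the threshold, or NA if all values are identical
#' @export
otsu_split <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2L) return(NA_real_)
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- cand[1]; best_bcv <- -Inf
  for (t in cand) {
    lo <- v[v <= t]; hi <- v[v > t]
    bcv <- length(lo) * length(hi) / length(v)^2 * (mean(hi) - mean(lo))^2
    if (bcv > best_bcv) { best_bcv <- bcv; best <- t }
  }
  best
}

#' Classify nucleus instances as healthy or apoptotic
#'
#' Computes the intensity standard deviation of each instance on the maximum
#' projection and splits the instances by 1-D Otsu thresholding of those
#' standard deviations; the higher-sd group (fragmented texture) is labeled
#' apoptotic. A single instance, or identical standard deviations, yields
#' all-healthy with a warning. `overrides` replicates the manual revision
#' step: a named character vector mapping instance label to state.
#'
#' @param instances a `vs_instances` object from [segment_instances()]
#' @param max_image matrix of intensities (the maximum projection)
#' @param overrides optional named vector, e.g. `c("3" = "apoptotic")`
#' @return the `vs_instances` with `states` set
#' @export
classify_states <- function(instances, max_image, overrides = NULL) {
  k <- max(instances$labels)
  if (k == 0L) { instances$states <- character(0); return(instances) }
  sds <- vapply(seq_len(k), function(i) {
    px <- max_image[instances$labels == i]
    if (length(px) < 2L) 0 else stats::sd(px)
  }, 0)
  if (k == 1L) {
    warning("single instance: Otsu split undefined, assigned healthy")
    states <- "healthy"
  } else {
    thr <- otsu_split(sds)
    if (is.na(thr)) {
      warning("identical standard deviations: all instances assigned healthy")
      states <- rep("healthy", k)
    } else {
      states <- ifelse(sds > thr, "apoptotic", "healthy")
    }
  }
  names(states) <- as.character(seq_len(k))
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(states))
    if (length(bad)) stop("override labels not present: ", paste(bad, collapse = ", "))
    states[names(overrides)] <- overrides
  }
  instances$states <- states
  instances$sds <- sds
  instances
}

#' Assemble a training sample from classified instances
#'
#' Channel 1 of the fluorescent target is the center slice masked by the
#' union of healthy instances, channel 2 by the union of apoptotic
#' instances; the class mask stores 0 = background, 1 = healthy,
#' 2 = apoptotic. The bright-field stack is min-max normalized per slice.
#'
#' @param center_slice matrix in \[0, 255\]: the CLAHE-enhanced center slice
#'   of the fluorescent z-stack
#' @param instances a `vs_instances` with states set
#' @param bf numeric array (H, W, S): raw bright-field stack
#' @return list with `bright_field` in \[0, 1\], `target` (H, W, 2) in \[0, 1\],
#'   `class_mask` (H, W) over \{0, 1, 2\}
#' @export
build_training_sample <- function(center_slice, instances, bf) {
  if (is.null(instances$states)) stop("instances must have states set")
  lab <- instances$labels
  healthy <- as.integer(names(instances$states)[instances$states == "healthy"])
  apop <- as.integer(names(instances$states)[instances$states == "apoptotic"])
  mh <- matrix(lab %in% healthy, nrow(lab), ncol(lab))
  ma <- matrix(lab %in% apop, nrow(lab), ncol(lab))
  tgt <- array(0, c(nrow(lab), ncol(lab), 2L))
  tgt[, , 1] <- center_slice * mh / 255
  tgt[, , 2] <- center_slice * ma / 255
  cm <- matrix(0L, nrow(lab), ncol(lab))
  cm[mh] <- 1L
  cm[ma] <- 2L
  nb <- bf
  if (length(dim(nb)) == 2L) dim(nb) <- c(dim(nb), 1L)
  for (s in seq_len(dim(nb)[3])) {
    sl <- nb[, , s]
    rng <- range(sl)
    nb[, , s] <- if (rng[2] > rng[1]) (sl - rng[1]) / (rng[2] - rng[1]) else 0
  }
  list(bright_field = nb, target = tgt, class_mask = cm)
}

#' Resize an image to a target size
#'
#' Shape-contract step of the preparation pipeline (raw acquisitions are
#' resized to a working resolution, default 512 x 512).
#'
#' @param img matrix or (H, W, C) array
#' @param h,w target dimensions
#' @return resized image of dim (h, w) or (h, w, C)
#' @export
resize_image <- function(img, h = 512L, w = 512L) {
  out <- EBImage::resize(EBImage::Image(img), w = h, h = w)
  d <- dim(img)
  if (length(d) == 2L) as.matrix(EBImage::imageData(out))
  else EBImage::imageData(out)
}
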