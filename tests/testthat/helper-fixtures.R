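# Shared fixtures and small oracles, all built in code at test time.

vs <- asNamespace("virtustain")

# tiny scene configuration used across tests (64 px, 5 nuclei); any field
# can be overridden through ...
tiny_scene_config <- function(seed = 11L, ...) {
  args <- list(height = 64L, width = 64L, n_healthy = 3L, n_apoptotic = 2L,
               nucleus_radius_range = c(5, 8), seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scene_config, args)
}

# deterministic pseudo-random array
rand_array <- function(dims, seed = 1L) {
  vs$with_seed(seed, array(stats::rnorm(prod(dims)), dims))
}

# dense brute-force attention oracle over all N^2 position pairs
oracle_self_attention <- function(x, m) {
  d <- dim(x)
  N <- d[1] * d[2]
  X <- t(matrix(x, N, d[3]))
  Q <- m$Wf$val %*% X
  K <- m$Wg$val %*% X
  V <- m$Wh$val %*% X
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    logits <- vapply(seq_len(N), function(j) sum(Q[, i] * K[, j]), 0)
    e <- exp(logits - max(logits))
    A[i, ] <- e / sum(e)
  }
  O <- matrix(0, d[3], N)
  for (i in seq_len(N)) O[, i] <- m$Wo$val %*% (V %*% A[i, ])
  x + m$gamma$val * array(t(O), d)
}

# cross-attention term oracle: query from x_img, key/value from x_msk
oracle_cross_term <- function(x_img, x_msk, mod) {
  d <- dim(x_img)
  N <- d[1] * d[2]
  Xi <- t(matrix(x_img, N, d[3]))
  Xm <- t(matrix(x_msk, N, d[3]))
  Q <- mod$img$Wf$val %*% Xi
  K <- mod$msk$Wg$val %*% Xm
  V <- mod$msk$Wh$val %*% Xm
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    logits <- vapply(seq_len(N), function(j) sum(Q[, i] * K[, j]), 0)
    e <- exp(logits - max(logits))
    A[i, ] <- e / sum(e)
  }
  O <- matrix(0, d[3], N)
  for (i in seq_len(N)) O[, i] <- mod$Woc$val %*% (V %*% A[i, ])
  array(t(O), d)
}

# fill all projection weights of an attention module with a deterministic
# small-integer pattern
fix_attention_weights <- function(m, scale = 0.25) {
  pat <- function(p, s) {
    v <- (seq_along(p$val) %% 5L - 2L) * scale * s
    p$val <- matrix(v, nrow(p$val), ncol(p$val))
  }
  pat(m$Wf, 1); pat(m$Wg, 0.8); pat(m$Wh, 0.6); pat(m$Wo, 0.5)
  invisible(m)
}

# disc image fixture: one or two discs on black, 8-bit range
disc_image <- function(H = 128L, centers, r = 20) {
  X <- matrix(seq_len(H), H, H)
  Y <- t(X)
  img <- matrix(0, H, H)
  for (cc in centers)
    img[sqrt((X - cc[1])^2 + (Y - cc[2])^2) <= r] <- 200
  img
}

n_components <- function(mask) max(EBImage::bwlabel(EBImage::Image(mask)))
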