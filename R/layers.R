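# Convolutional layer containers and the optimizer. A "layer" is a list of
# parameter environments plus static hyper-parameters; forward functions build
# autodiff nodes. Spectral normalization is applied to every convolution
# weight in both networks, with one power iteration per training step and a
# configurable number of iterations elsewhere.

.vs_rng <- local({
  # scaled Gaussian init (He-style fan-in scaling)
  function(n, fan_in) stats::rnorm(n, sd = sqrt(2 / max(1, fan_in)))
})

#' @keywords internal
new_conv <- function(ci, co, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                     sn = TRUE, name = "conv") {
  W <- matrix(.vs_rng(co * k * k * ci, k * k * ci), co, k * k * ci)
  list(kind = "conv", W = new_param(W, paste0(name, ".W")),
       b = new_param(numeric(co), paste0(name, ".b")),
       ci = ci, co = co, k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), sn = sn)
}

#' @keywords internal
new_convT <- function(ci, co, k = 4L, stride = 2L, pad = 1L,
                      sn = TRUE, name = "convT") {
  W <- matrix(.vs_rng(ci * k * k * co, k * k * ci), ci, k * k * co)
  list(kind = "convT", W = new_param(W, paste0(name, ".W")),
       b = new_param(numeric(co), paste0(name, ".b")),
       ci = ci, co = co, k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), sn = sn)
}

# weight leaf honoring the layer's spectral-norm flag
conv_wleaf <- function(layer, sn_iter = 1L) {
  if (isTRUE(layer$sn)) ad_sn_leaf(layer$W, sn_iter) else ad_leaf(layer$W)
}

conv_fwd <- function(layer, x, sn_iter = 1L) {
  wn <- conv_wleaf(layer, sn_iter)
  bn <- ad_leaf(layer$b)
  if (layer$kind == "conv") {
    ad_conv2d(x, wn, bn, layer$k, layer$k, layer$stride, layer$pad)
  } else {
    ad_convT2d(x, wn, bn, layer$co, layer$k, layer$k, layer$stride, layer$pad)
  }
}

layer_params <- function(layer) list(layer$W, layer$b)

#' Spectrally normalize a weight matrix
#'
#' Divides a weight matrix (convolution kernels reshaped to 2-D) by its
#' largest singular value, estimated by power iteration. Used throughout the
#' generator and discriminator to stabilize adversarial training; exposed for
#' inspection and testing.
#'
#' @param weight numeric matrix
#' @param n_iter number of power iterations (>= 5 gives a tight estimate)
#' @return the normalized matrix, with largest singular value ~ 1
#' @export
#' @examples
#' w <- diag(c(2, 1))
#' spectral_normalize(w, n_iter = 10)
spectral_normalize <- function(weight, n_iter = 5L) {
  if (!is.matrix(weight)) weight <- as.matrix(weight)
  if (all(weight == 0)) {
    warning("spectral_normalize: all-zero weight, returned unchanged")
    return(weight)
  }
  p <- new_param(weight)
  s <- sn_sigma(p, n_iter)
  weight / s$sigma
}

# ---- optimizer ------------------------------------------------------------

#' @keywords internal
new_adam <- function(params, lr = 1e-4, betas = c(0.5, 0.999), eps = 1e-8) {
  list(params = params, lr = lr, b1 = betas[1], b2 = betas[2], eps = eps,
       t = new.env(parent = emptyenv()))
}

adam_step <- function(opt) {
  tt <- (opt$t$i %||% 0L) + 1L
  opt$t$i <- tt
  c1 <- 1 - opt$b1^tt
  c2 <- 1 - opt$b2^tt
  for (p in opt$params) {
    g <- p$grad
    p$m <- opt$b1 * p$m + (1 - opt$b1) * g
    p$v <- opt$b2 * p$v + (1 - opt$b2) * g * g
    p$val <- p$val - opt$lr * (p$m / c1) / (sqrt(p$v / c2) + opt$eps)
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- p$grad * 0
  invisible(NULL)
}

# flatten a nested structure of parameter environments into a list
collect_params <- function(x) {
  out <- list()
  walk <- function(e) {
    if (inherits(e, "vs_param")) {
      out[[length(out) + 1L]] <<- e
    } else if (is.list(e)) {
      for (el in e) walk(el)
    }
  }
  walk(x)
  out
}

param_count <- function(params) sum(vapply(params, function(p) length(p$val), 0))
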