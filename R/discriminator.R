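# Conditional PatchGAN discriminator. The bright-field stack (condition) and
# a 2-channel fluorescent image are concatenated along channels and reduced
# by residual down-sampling sub-modules; the final 1-channel convolution
# emits a grid of patch logits, each judging a bounded sub-window of the
# input. Self-attention can be inserted after the deeper levels; all
# convolution weights are spectrally normalized.

#' Discriminator configuration
#'
#' @param input_slices bright-field slices S (condition channels)
#' @param image_channels fluorescent image channels (2)
#' @param base_channels channels after the first down-sampling sub-module
#' @param n_down number of down-sampling sub-modules (patch grid is the
#'   input reduced 2^n_down times)
#' @param attention_levels integer indices of levels after which a
#'   self-attention module is applied (deeper levels by default)
#' @param sn apply spectral normalization?
#' @return a `vs_discriminator_config` list
#' @export
discriminator_config <- function(input_slices = 13L, image_channels = 2L,
                                 base_channels = 32L, n_down = 4L,
                                 attention_levels = c(3L, 4L), sn = TRUE) {
  structure(list(input_slices = as.integer(input_slices),
                 image_channels = as.integer(image_channels),
                 base_channels = as.integer(base_channels),
                 n_down = as.integer(n_down),
                 attention_levels = as.integer(attention_levels), sn = sn),
            class = "vs_discriminator_config")
}

#' Build the PatchGAN discriminator
#' @param config a [discriminator_config()]
#' @return an object of class `vs_discriminator`
#' @export
build_discriminator <- function(config) {
  b <- config$base_channels
  ch <- b * 2L^(seq_len(config$n_down) - 1L)
  blocks <- vector("list", config$n_down)
  attn <- vector("list", config$n_down)
  ci <- config$input_slices + config$image_channels
  for (i in seq_len(config$n_down)) {
    blocks[[i]] <- new_down_block(ci, ch[i], config$sn, name = paste0("d", i))
    if (i %in% config$attention_levels)
      attn[[i]] <- new_self_attention(ch[i], sn = config$sn)
    ci <- ch[i]
  }
  d <- list(config = config, blocks = blocks, attn = attn,
            head = new_conv(ch[config$n_down], 1L, k = 3L, stride = 1L,
                            sn = config$sn, name = "d.head"))
  d$params <- collect_params(d[c("blocks", "attn", "head")])
  class(d) <- "vs_discriminator"
  d
}

disc_fwd <- function(d, x, sn_iter = 1L) {
  h <- x
  for (i in seq_along(d$blocks)) {
    h <- down_fwd(d$blocks[[i]], h, sn_iter)
    if (!is.null(d$attn[[i]])) h <- sa_fwd(d$attn[[i]], h, sn_iter)
  }
  conv_fwd(d$head, h, sn_iter)
}

#' Score a bright-field / fluorescence pair patchwise
#'
#' @param d a `vs_discriminator`
#' @param x bright-field stack, array (H, W, S)
#' @param y fluorescent image, array (H, W, image_channels)
#' @param sn_iter power iterations for spectral normalization
#' @return matrix of patch logits (H / 2^n_down by W / 2^n_down)
#' @export
discriminate <- function(d, x, y, sn_iter = 1L) {
  if (!all(dim(x)[1:2] == dim(y)[1:2]))
    stop("bright-field stack and image must share spatial dimensions")
  ad_begin(grad = FALSE)
  xin <- array(c(x, y), c(dim(x)[1], dim(x)[2], dim(x)[3] + dim(y)[3]))
  out <- disc_fwd(d, ad_const(xin), sn_iter)
  out$val[, , 1]
}
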