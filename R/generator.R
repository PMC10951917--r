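# Dual-path encoder-decoder generator.
#
# One shared encoder (5 residual down-sampling sub-modules + bottleneck)
# feeds two decoders (image translation and mask segmentation), each of 5
# residual up-sampling sub-modules with encoder skip connections. Attention
# modules sit at the 4 intervals between adjacent up-sampling sub-modules;
# a 4-digit binary placement code selects which intervals are occupied
# (digit 1 = between the two deepest up-sampling sub-modules). The image
# head ends in Tanh (values in [-1, 1]); the mask head ends in a 3-class
# SoftMax (healthy, apoptotic, background); the translation result gates
# each image channel by the matching mask probability.

#' Generator configuration
#'
#' @param placement 4-character placement code over \{0,1\}; digit i = 1
#'   puts an attention module at decoder interval i (interval 1 is between
#'   the two deepest up-sampling sub-modules, interval 4 nearest the output)
#' @param input_slices number of bright-field slices S (conditioning input)
#' @param base_channels channels after the first down-sampling sub-module;
#'   doubled at every level (so the bottleneck carries 16x this)
#' @param variant `"dual"` (two decoders joined by cross-attention),
#'   `"single_1ch"` or `"single_2ch"` (single decoder with plain
#'   self-attention at the flagged intervals and no mask path; 1- or
#'   2-channel image output)
#' @param sn apply spectral normalization to convolution weights?
#' @return a `vs_generator_config` list
#' @export
generator_config <- function(placement = "0011", input_slices = 13L,
                             base_channels = 32L,
                             variant = c("dual", "single_1ch", "single_2ch"),
                             sn = TRUE) {
  variant <- match.arg(variant)
  if (!grepl("^[01]{4}$", placement))
    stop("placement must be a 4-digit binary string, e.g. \"0011\"")
  structure(list(placement = placement, input_slices = as.integer(input_slices),
                 base_channels = as.integer(base_channels), levels = 5L,
                 variant = variant, sn = sn),
            class = "vs_generator_config")
}

new_down_block <- function(ci, co, sn = TRUE, name = "down") {
  list(convA = new_conv(ci, co, k = 3L, stride = 1L, sn = sn, name = paste0(name, ".A")),
       convB = new_conv(co, co, k = 4L, stride = 2L, pad = 1L, sn = sn, name = paste0(name, ".B")),
       short = new_conv(ci, co, k = 1L, stride = 2L, pad = 0L, sn = sn, name = paste0(name, ".S")))
}

down_fwd <- function(blk, x, sn_iter = 1L) {
  d <- dim(x$val)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop("down-sampling sub-module needs even spatial dimensions")
  h <- ad_lrelu(conv_fwd(blk$convA, x, sn_iter))
  h <- conv_fwd(blk$convB, h, sn_iter)
  s <- conv_fwd(blk$short, x, sn_iter)
  ad_lrelu(ad_add(h, s))
}

new_up_block <- function(ci, cskip, co, sn = TRUE, name = "up") {
  list(up = new_convT(ci, co, k = 4L, stride = 2L, pad = 1L, sn = sn, name = paste0(name, ".T")),
       convA = new_conv(co + cskip, co, k = 3L, stride = 1L, sn = sn, name = paste0(name, ".A")),
       short = new_conv(ci, co, k = 1L, stride = 1L, pad = 0L, sn = sn, name = paste0(name, ".S")),
       cskip = as.integer(cskip))
}

up_fwd <- function(blk, x, skip, sn_iter = 1L) {
  u <- conv_fwd(blk$up, x, sn_iter)
  if (blk$cskip > 0L) {
    if (is.null(skip) || !all(dim(skip$val)[1:2] == dim(u$val)[1:2]))
      stop("up-sampling sub-module: skip spatial dimensions must be 2x the input")
    u <- ad_concat_c(u, skip)
  }
  y <- conv_fwd(blk$convA, u, sn_iter)
  s <- conv_fwd(blk$short, ad_upsample2_nn(x), sn_iter)
  ad_relu(ad_add(y, s))
}

new_bottleneck <- function(c, sn = TRUE) {
  list(convA = new_conv(c, c, k = 3L, stride = 1L, sn = sn, name = "bn.A"),
       convB = new_conv(c, c, k = 3L, stride = 1L, sn = sn, name = "bn.B"))
}

bottleneck_fwd <- function(blk, x, sn_iter = 1L) {
  h <- ad_lrelu(conv_fwd(blk$convA, x, sn_iter))
  ad_lrelu(ad_add(conv_fwd(blk$convB, h, sn_iter), x))
}

#' Build the translation generator
#'
#' @param config a [generator_config()]
#' @return an object of class `vs_generator`
#' @export
build_generator <- function(config) {
  b <- config$base_channels
  sn <- config$sn
  enc_ch <- b * c(1L, 2L, 4L, 8L, 16L)
  dec_ch <- b * c(8L, 4L, 2L, 1L, 1L)
  enc <- vector("list", 5L)
  ci <- config$input_slices
  for (i in 1:5) {
    enc[[i]] <- new_down_block(ci, enc_ch[i], sn, name = paste0("enc", i))
    ci <- enc_ch[i]
  }
  bott <- new_bottleneck(enc_ch[5], sn)
  make_decoder <- function(tag) {
    dec <- vector("list", 5L)
    ci <- enc_ch[5]
    for (j in 1:5) {
      cskip <- if (j < 5L) enc_ch[5L - j] else 0L
      dec[[j]] <- new_up_block(ci, cskip, dec_ch[j], sn, name = paste0(tag, j))
      ci <- dec_ch[j]
    }
    dec
  }
  flags <- as.integer(strsplit(config$placement, "")[[1]])
  attn <- vector("list", 4L)
  dual <- config$variant == "dual"
  for (i in 1:4) {
    if (flags[i] == 1L) {
      attn[[i]] <- if (dual) new_cross_attention(dec_ch[i], sn = sn)
                   else new_self_attention(dec_ch[i], sn = sn)
    }
  }
  img_channels <- if (config$variant == "single_1ch") 1L else 2L
  g <- list(
    config = config,
    enc = enc, bottleneck = bott,
    dec_img = make_decoder("img"),
    dec_msk = if (dual) make_decoder("msk") else NULL,
    attn = attn,
    head_img = new_conv(dec_ch[5], img_channels, k = 1L, pad = 0L, sn = FALSE, name = "head.img"),
    head_msk = if (dual) new_conv(dec_ch[5], 3L, k = 1L, pad = 0L, sn = FALSE, name = "head.msk") else NULL)
  g$params <- collect_params(g[c("enc", "bottleneck", "dec_img", "dec_msk",
                                 "attn", "head_img", "head_msk")])
  class(g) <- "vs_generator"
  g
}

#' @export
print.vs_generator <- function(x, ...) {
  cat(sprintf("<vs_generator> variant=%s placement=%s slices=%d base=%d params=%d\n",
              x$config$variant, x$config$placement, x$config$input_slices,
              x$config$base_channels, param_count(x$params)))
  invisible(x)
}

#' Number of attention modules instantiated by a generator
#' @param g a `vs_generator`
#' @return integer count
#' @export
n_attention_modules <- function(g) sum(!vapply(g$attn, is.null, TRUE))

# channel softmax over the 3rd dimension of an (H,W,C) node
ad_softmax_c <- function(a) {
  d <- dim(a$val)
  n <- d[1] * d[2]
  V <- matrix(a$val, n, d[3])
  E <- exp(V - rowmax(V))
  Y <- E / rowSums(E)
  y <- array(Y, d)
  ad_node(y, function(g) {
    G <- matrix(g, n, d[3])
    ad_acc(a, array(Y * (G - rowSums(G * Y)), d))
  })
}

# gate the image channels by the matching mask probabilities (background
# channel gates nothing)
ad_gate <- function(img, mask) {
  ic <- dim(img$val)[3]
  mv <- mask$val[, , seq_len(ic), drop = FALSE]
  iv <- img$val
  ad_node(iv * mv, function(g) {
    ad_acc(img, g * mv)
    dm <- array(0, dim(mask$val))
    dm[, , seq_len(ic)] <- g * iv
    ad_acc(mask, dm)
  })
}

# Full generator forward on nodes. Returns image, mask logits/probabilities
# and the gated translation (single-path variants return mask = NULL and
# translation = image).
gen_fwd <- function(g, x, sn_iter = 1L) {
  cfg <- g$config
  e <- vector("list", 5L)
  h <- x
  for (i in 1:5) {
    e[[i]] <- down_fwd(g$enc[[i]], h, sn_iter)
    h <- e[[i]]
  }
  h <- bottleneck_fwd(g$bottleneck, h, sn_iter)
  dual <- cfg$variant == "dual"
  di <- h
  dm <- if (dual) h else NULL
  for (j in 1:5) {
    skip <- if (j < 5L) e[[5L - j]] else NULL
    di <- up_fwd(g$dec_img[[j]], di, skip, sn_iter)
    if (dual) dm <- up_fwd(g$dec_msk[[j]], dm, skip, sn_iter)
    if (j < 5L && !is.null(g$attn[[j]])) {
      if (dual) {
        out <- xa_fwd(g$attn[[j]], di, dm, sn_iter)
        di <- out$img; dm <- out$msk
      } else {
        di <- sa_fwd(g$attn[[j]], di, sn_iter)
      }
    }
  }
  image <- ad_tanh(conv_fwd(g$head_img, di, sn_iter))
  if (dual) {
    mask_logits <- conv_fwd(g$head_msk, dm, sn_iter)
    mask <- ad_softmax_c(mask_logits)
    list(image = image, mask_logits = mask_logits, mask = mask,
         translation = ad_gate(image, mask))
  } else {
    list(image = image, mask_logits = NULL, mask = NULL, translation = image)
  }
}

#' Translate a bright-field stack
#'
#' Runs the generator forward. The returned `translation` is the per-channel
#' product of the image output and the matching mask probability (dual
#' variant); for single-path variants it equals the image output.
#'
#' @param g a `vs_generator`
#' @param x numeric array of dim (H, W, S): min-max normalized bright-field
#'   stack with values in \[0, 1\]; H and W must be divisible by 32
#' @param sn_iter power iterations for spectral normalization
#' @return list with `image` (H, W, 2 or 1) in \[-1, 1\], `mask` (H, W, 3)
#'   per-pixel probabilities summing to 1 (or NULL), and `translation`
#' @export
generate <- function(g, x, sn_iter = 1L) {
  d <- dim(x)
  if (length(d) != 3L) stop("x must be an (H, W, S) array")
  if (d[3] != g$config$input_slices)
    stop(sprintf("stack has %d slices but the generator expects %d", d[3],
                 g$config$input_slices))
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop(sprintf(paste0("spatial dimensions must be divisible by 32 ",
                        "(got %dx%d); pad to %dx%d"),
                 d[1], d[2], 32L * ceiling(d[1] / 32), 32L * ceiling(d[2] / 32)))
  ad_begin(grad = FALSE)
  out <- gen_fwd(g, ad_const(x), sn_iter)
  list(image = out$image$val,
       mask = if (is.null(out$mask)) NULL else out$mask$val,
       translation = out$translation$val)
}
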