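# Self-attention and cross-attention feature-map operators.
#
# Both operators act on (H, W, C) feature maps flattened to N = H*W spatial
# positions. Query/key projections reduce channels by `reduction_factor`
# (SAGAN convention C/8, minimum 1); the value projection uses max(C/2, 1)
# channels and a final 1x1 projection restores C. The attended output is
# added back through a learnable scalar gamma initialized at 0, so every
# module is an exact identity at initialization.

attn_dims <- function(channels, reduction_factor) {
  cq <- max(1L, channels %/% reduction_factor)
  cv <- max(1L, channels %/% 2L)
  list(cq = cq, cv = cv)
}

#' Create a self-attention module
#'
#' Holds the four 1x1 projection weights (query f, key g, value h, output o)
#' and the learnable residual scale gamma (initialized to 0 so the module
#' starts as an identity).
#'
#' @param channels number of input/output channels C
#' @param reduction_factor channel reduction for the query/key projections
#'   (projection width is `max(1, C %/% reduction_factor)`)
#' @param sn apply spectral normalization to the projection weights?
#' @return an object of class `vs_self_attention`
#' @export
new_self_attention <- function(channels, reduction_factor = 8L, sn = TRUE) {
  if (channels < 1L) stop("attention requires >= 1 channel")
  d <- attn_dims(channels, reduction_factor)
  m <- list(
    channels = as.integer(channels),
    reduction_factor = as.integer(reduction_factor),
    cq = d$cq, cv = d$cv, sn = sn,
    Wf = new_param(matrix(.vs_rng(d$cq * channels, channels), d$cq, channels), "attn.Wf"),
    Wg = new_param(matrix(.vs_rng(d$cq * channels, channels), d$cq, channels), "attn.Wg"),
    Wh = new_param(matrix(.vs_rng(d$cv * channels, channels), d$cv, channels), "attn.Wh"),
    Wo = new_param(matrix(.vs_rng(channels * d$cv, d$cv), channels, d$cv), "attn.Wo"),
    gamma = new_param(0, "attn.gamma"))
  class(m) <- "vs_self_attention"
  m
}

attn_wleaf <- function(m, p, sn_iter) {
  if (isTRUE(m$sn)) ad_sn_leaf(p, sn_iter) else ad_leaf(p)
}

# attended map o(x) (before gamma/residual), matrix domain: xm is (C, N)
attn_core <- function(q_mod, kv_mod, xm_q, xm_kv, wo_param, sn_iter) {
  Q <- ad_mm(attn_wleaf(q_mod, q_mod$Wf, sn_iter), xm_q)     # (Cq, N)
  K <- ad_mm(attn_wleaf(kv_mod, kv_mod$Wg, sn_iter), xm_kv)  # (Cq, N)
  V <- ad_mm(attn_wleaf(kv_mod, kv_mod$Wh, sn_iter), xm_kv)  # (Cv, N)
  A <- ad_softmax_rows(ad_crossprod(Q, K))                   # (N, N), rows sum to 1
  att <- ad_tcrossprod(V, A)                                 # (Cv, N)
  wo <- if (isTRUE(q_mod$sn)) ad_sn_leaf(wo_param, sn_iter) else ad_leaf(wo_param)
  ad_mm(wo, att)                                             # (C, N)
}

# node-level self-attention forward: x + gamma * o(x)
sa_fwd <- function(m, x, sn_iter = 1L) {
  d <- dim(x$val)
  if (d[3] != m$channels) stop("self-attention: channel mismatch (configuration error)")
  if (d[1] * d[2] < 1L) stop("self-attention: empty spatial grid")
  xm <- ad_map2mat(x)
  o <- ad_mat2map(attn_core(m, m, xm, xm, m$Wo, sn_iter), d[1], d[2])
  ad_add(x, ad_scale_p(o, m$gamma))
}

#' Apply self-attention to a feature map
#'
#' Computes `x + gamma * o(x)` where `o(x)` is the dense attended map:
#' 1x1 query/key/value projections, attention logits over all pairs of
#' spatial positions, row-wise softmax, value-weighted sum, and a final 1x1
#' projection restoring the channel count.
#'
#' @param x numeric array of dim (H, W, C)
#' @param module a `vs_self_attention` module
#' @param sn_iter power iterations used for spectral normalization
#' @return array of the same shape as `x`
#' @export
self_attention <- function(x, module, sn_iter = 5L) {
  if (length(dim(x)) != 3L) stop("x must be an (H, W, C) array")
  ad_begin(grad = FALSE)
  sa_fwd(module, ad_const(x), sn_iter)$val
}

#' Create a cross-attention module
#'
#' Two self-attention paths (image and mask) plus a cross term that takes its
#' query from the image path and key/value from the mask path, reusing those
#' paths' projections. The cross output has its own final 1x1 projection and
#' its own gamma. The image output is a 1x1 projection of the concatenation
#' of the two residual branches; that projection is initialized to average
#' the two halves, so the whole module is an identity while all gammas are 0.
#'
#' @inheritParams new_self_attention
#' @return an object of class `vs_cross_attention` with fields `img`, `msk`
#'   (self-attention modules), `Woc`, `gamma_c` (cross term), `Wproj`
#' @export
new_cross_attention <- function(channels, reduction_factor = 8L, sn = TRUE) {
  d <- attn_dims(channels, reduction_factor)
  proj <- cbind(diag(channels) / 2, diag(channels) / 2)
  m <- list(
    channels = as.integer(channels),
    img = new_self_attention(channels, reduction_factor, sn),
    msk = new_self_attention(channels, reduction_factor, sn),
    Woc = new_param(matrix(.vs_rng(channels * d$cv, d$cv), channels, d$cv), "xattn.Woc"),
    gamma_c = new_param(0, "xattn.gamma_c"),
    Wproj = new_param(proj, "xattn.Wproj"),
    sn = sn)
  class(m) <- "vs_cross_attention"
  m
}

# node-level cross-attention forward; returns list(img, msk)
xa_fwd <- function(m, x_img, x_msk, sn_iter = 1L) {
  di <- dim(x_img$val); dm <- dim(x_msk$val)
  if (!all(di[1:2] == dm[1:2]))
    stop("cross-attention: image and mask paths must share spatial dimensions")
  xi <- ad_map2mat(x_img)
  xm <- ad_map2mat(x_msk)
  o_self <- ad_mat2map(attn_core(m$img, m$img, xi, xi, m$img$Wo, sn_iter), di[1], di[2])
  o_msk  <- ad_mat2map(attn_core(m$msk, m$msk, xm, xm, m$msk$Wo, sn_iter), dm[1], dm[2])
  o_cross <- ad_mat2map(attn_core(m$img, m$msk, xi, xm, m$Woc, sn_iter), di[1], di[2])
  half1 <- ad_add(x_img, ad_scale_p(o_self, m$img$gamma))
  half2 <- ad_add(x_img, ad_scale_p(o_cross, m$gamma_c))
  # Wproj is not spectrally normalized: its averaging initialization is the
  # identity-preserving reference point.
  y_img_m <- ad_mm(ad_leaf(m$Wproj),
                   ad_concat_rows(ad_map2mat(half1), ad_map2mat(half2)))
  list(img = ad_mat2map(y_img_m, di[1], di[2]),
       msk = ad_add(x_msk, ad_scale_p(o_msk, m$msk$gamma)))
}

#' Apply cross-attention to paired image/mask feature maps
#'
#' @param x_img,x_mask numeric arrays of dim (H, W, C) from the image and
#'   mask decoders at the same level
#' @param module a `vs_cross_attention` module
#' @param sn_iter power iterations used for spectral normalization
#' @return list with elements `img` and `msk`, same shapes as the inputs
#' @export
cross_attention <- function(x_img, x_mask, module, sn_iter = 5L) {
  ad_begin(grad = FALSE)
  out <- xa_fwd(module, ad_const(x_img), ad_const(x_mask), sn_iter)
  list(img = out$img$val, msk = out$msk$val)
}
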