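# Reverse-mode automatic differentiation on dense image tensors.
#
# Tensors are plain R arrays with dim c(H, W, C) ("map" nodes), matrices
# ("mat" nodes) or scalars. A node is an environment holding the value, the
# accumulated gradient, and a backward closure; nodes created while the tape
# is active are recorded in creation order and visited in reverse by
# ad_backward(). Parameters are separate environments (see new_param) whose
# gradients persist across tapes until zeroed by the optimizer.

.vt <- new.env(parent = emptyenv())
.vt$tape <- list()
.vt$n <- 0L
.vt$grad <- FALSE

#' Start a fresh autodiff tape
#'
#' Clears the recording tape. With `grad = FALSE` subsequent operations run
#' forward-only (no backward closures are retained), which is used for
#' inference and for producing detached generator outputs during the
#' discriminator step.
#'
#' @param grad logical; record operations for backpropagation?
#' @return invisibly, NULL
#' @keywords internal
ad_begin <- function(grad = TRUE) {
  .vt$tape <- vector("list", 64L)
  .vt$n <- 0L
  .vt$grad <- isTRUE(grad)
  invisible(NULL)
}

ad_node <- function(val, bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  if (.vt$grad && !is.null(bw)) {
    nd$bw <- bw
    n <- .vt$n + 1L
    if (n > length(.vt$tape)) length(.vt$tape) <- 2L * n
    .vt$tape[[n]] <- nd
    .vt$n <- n
  }
  nd
}

ad_const <- function(val) ad_node(val, NULL)

ad_is_node <- function(x) is.environment(x) && !is.null(x$val)

ad_val <- function(x) if (ad_is_node(x)) x$val else x

ad_acc <- function(nd, g) {
  if (is.null(nd)) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

#' Backpropagate from a scalar loss node
#' @param out scalar output node
#' @keywords internal
ad_backward <- function(out) {
  out$grad <- 1
  if (.vt$n > 0L) {
    for (i in rev(seq_len(.vt$n))) {
      nd <- .vt$tape[[i]]
      if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
    }
  }
  invisible(NULL)
}

# ---- trainable parameters -------------------------------------------------

#' Create a trainable parameter
#' @param val initial numeric value (scalar, vector or matrix)
#' @param name optional label used in diagnostics
#' @keywords internal
new_param <- function(val, name = "") {
  p <- new.env(parent = emptyenv())
  p$val <- val
  p$grad <- val * 0
  p$m <- val * 0
  p$v <- val * 0
  p$u <- NULL          # persistent power-iteration vector (spectral norm)
  p$name <- name
  class(p) <- "vs_param"
  p
}

# Leaf node for a parameter used as-is (no spectral normalization).
ad_leaf <- function(p) {
  force(p)
  ad_node(p$val, function(g) p$grad <- p$grad + g)
}

# Leaf node for a spectrally normalized weight matrix. sigma is estimated by
# power iteration with a persistent left vector stored on the parameter; the
# gradient includes the d(sigma)/dW = u v^T term.
ad_sn_leaf <- function(p, n_iter = 1L) {
  force(p)
  sn <- sn_sigma(p, n_iter)
  sigma <- sn$sigma
  if (sigma <= 0) return(ad_leaf(p))
  u <- sn$u; v <- sn$v
  what <- p$val / sigma
  ad_node(what, function(g) {
    corr <- sum(g * what) / sigma
    p$grad <- p$grad + g / sigma - corr * (u %*% t(v))
  })
}

# Power iteration estimate of the top singular value of a parameter matrix,
# updating the persistent u vector in place.
sn_sigma <- function(p, n_iter = 1L) {
  W <- p$val
  if (!is.matrix(W)) W <- matrix(W, nrow = 1L)
  if (all(W == 0)) {
    warning("spectral normalization skipped: all-zero weight")
    return(list(sigma = 0, u = NULL, v = NULL))
  }
  u <- p$u
  if (is.null(u) || length(u) != nrow(W)) {
    u <- rep(1, nrow(W)) / sqrt(nrow(W))
  }
  v <- NULL
  sigma_prev <- -Inf
  for (i in seq_len(max(1L, n_iter))) {
    v <- drop(crossprod(W, u)); v <- v / sqrt(sum(v^2) + 1e-12)
    u <- drop(W %*% v);         u <- u / sqrt(sum(u^2) + 1e-12)
    if (n_iter > 1L) {
      sigma <- drop(t(u) %*% W %*% v)
      if (abs(sigma - sigma_prev) < 1e-12 * max(1, abs(sigma))) break
      sigma_prev <- sigma
    }
  }
  p$u <- u
  list(sigma = max(drop(t(u) %*% W %*% v), 1e-12), u = u, v = v)
}

# ---- elementwise / shape ops ---------------------------------------------

ad_add <- function(a, b) {
  ad_node(a$val + b$val, function(g) { ad_acc(a, g); ad_acc(b, g) })
}

ad_sub <- function(a, b) {
  ad_node(a$val - b$val, function(g) { ad_acc(a, g); ad_acc(b, -g) })
}

ad_mul <- function(a, b) {
  av <- a$val; bv <- b$val
  ad_node(av * bv, function(g) { ad_acc(a, g * bv); ad_acc(b, g * av) })
}

ad_div <- function(a, b) {
  av <- a$val; bv <- b$val
  y <- av / bv
  ad_node(y, function(g) { ad_acc(a, g / bv); ad_acc(b, -g * y / bv) })
}

ad_cadd <- function(a, k) ad_node(a$val + k, function(g) ad_acc(a, g))

ad_cmul <- function(a, k) ad_node(a$val * k, function(g) ad_acc(a, g * k))

ad_relu <- function(a) {
  m <- a$val > 0
  ad_node(a$val * m, function(g) ad_acc(a, g * m))
}

ad_lrelu <- function(a, slope = 0.2) {
  m <- slope + (1 - slope) * (a$val > 0)
  ad_node(a$val * m, function(g) ad_acc(a, g * m))
}

ad_tanh <- function(a) {
  y <- tanh(a$val)
  ad_node(y, function(g) ad_acc(a, g * (1 - y^2)))
}

ad_mean <- function(a) {
  n <- length(a$val)
  ad_node(mean(a$val), function(g) ad_acc(a, array(g / n, dim(a$val) %||% n)))
}

ad_mean_abs <- function(a) {
  n <- length(a$val)
  s <- sign(a$val)
  ad_node(mean(abs(a$val)), function(g) ad_acc(a, (g / n) * s))
}

# sum_i coef_i * node_i for scalar nodes
ad_lincomb <- function(nodes, coefs) {
  v <- 0
  for (i in seq_along(nodes)) v <- v + coefs[i] * nodes[[i]]$val
  ad_node(v, function(g) for (i in seq_along(nodes)) ad_acc(nodes[[i]], g * coefs[i]))
}

# multiply a (H,W,C) node by a learnable scalar parameter
ad_scale_p <- function(a, p) {
  av <- a$val; pv <- p$val
  ad_node(av * pv, function(g) {
    ad_acc(a, g * pv)
    p$grad <- p$grad + sum(g * av)
  })
}

# concatenate two (H,W,*) nodes along channels
ad_concat_c <- function(a, b) {
  da <- dim(a$val); db <- dim(b$val)
  y <- array(0, c(da[1], da[2], da[3] + db[3]))
  y[, , seq_len(da[3])] <- a$val
  y[, , da[3] + seq_len(db[3])] <- b$val
  ad_node(y, function(g) {
    ad_acc(a, g[, , seq_len(da[3]), drop = FALSE])
    ad_acc(b, g[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

ad_upsample2_nn <- function(a) {
  d <- dim(a$val)
  y <- vs_upsample2(a$val, d[1], d[2], d[3])
  ad_node(y, function(g) ad_acc(a, vs_downsum2(g, 2L * d[1], 2L * d[2], d[3])))
}

# reshape (H,W,C) map node to a (C, N) matrix node (N = H*W positions)
ad_map2mat <- function(a) {
  d <- dim(a$val)
  N <- d[1] * d[2]
  m <- t(matrix(a$val, N, d[3]))
  ad_node(m, function(g) ad_acc(a, array(t(g), d)))
}

# reshape (C, N) matrix node back to an (H,W,C) map
ad_mat2map <- function(a, H, W) {
  d <- dim(a$val)
  ad_node(array(t(a$val), c(H, W, d[1])),
          function(g) ad_acc(a, t(matrix(g, H * W, d[1]))))
}

ad_concat_rows <- function(a, b) {
  na <- nrow(a$val)
  ad_node(rbind(a$val, b$val), function(g) {
    ad_acc(a, g[seq_len(na), , drop = FALSE])
    ad_acc(b, g[-seq_len(na), , drop = FALSE])
  })
}

# ---- matrix ops (attention) ----------------------------------------------

ad_mm <- function(a, b) {
  av <- a$val; bv <- b$val
  ad_node(av %*% bv, function(g) {
    ad_acc(a, tcrossprod(g, bv))
    ad_acc(b, crossprod(av, g))
  })
}

# Y = t(A) %*% B without materializing the transpose
ad_crossprod <- function(a, b) {
  av <- a$val; bv <- b$val
  ad_node(crossprod(av, bv), function(g) {
    ad_acc(a, tcrossprod(bv, g))
    ad_acc(b, av %*% g)
  })
}

# Y = A %*% t(B) without materializing the transpose
ad_tcrossprod <- function(a, b) {
  av <- a$val; bv <- b$val
  ad_node(tcrossprod(av, bv), function(g) {
    ad_acc(a, g %*% bv)
    ad_acc(b, crossprod(g, av))
  })
}

ad_t <- function(a) ad_node(t(a$val), function(g) ad_acc(a, t(g)))

rowmax <- function(v) v[cbind(seq_len(nrow(v)), max.col(v, ties.method = "first"))]

# numerically stable row-wise softmax of a matrix node
ad_softmax_rows <- function(a) {
  v <- a$val
  e <- exp(v - rowmax(v))
  y <- e / rowSums(e)
  ad_node(y, function(g) {
    ad_acc(a, y * (g - rowSums(g * y)))
  })
}

# ---- convolutions ---------------------------------------------------------

# 2-D convolution of an (H,W,C) node. wnode is a (Co, kh*kw*Ci) weight leaf,
# bnode a length-Co bias leaf (or NULL).
ad_conv2d <- function(x, wnode, bnode, kh, kw, stride, pad) {
  d <- dim(x$val)
  H <- d[1]; W <- d[2]; Ci <- d[3]
  cols <- vs_im2col(x$val, H, W, Ci, kh, kw, stride, pad)
  Ho <- (H + 2L * pad - kh) %/% stride + 1L
  Wo <- (W + 2L * pad - kw) %/% stride + 1L
  Y <- wnode$val %*% cols
  if (!is.null(bnode)) Y <- Y + bnode$val
  Co <- nrow(wnode$val)
  ad_node(array(t(Y), c(Ho, Wo, Co)), function(g) {
    gm <- t(matrix(g, Ho * Wo, Co))
    ad_acc(wnode, gm %*% t(cols))
    if (!is.null(bnode)) ad_acc(bnode, rowSums(gm))
    dcols <- crossprod(wnode$val, gm)
    ad_acc(x, vs_col2im(dcols, H, W, Ci, kh, kw, stride, pad))
  })
}

# Transposed 2-D convolution (stride-2 upsampling). wnode is (Ci, kh*kw*Co).
ad_convT2d <- function(x, wnode, bnode, co, kh, kw, stride, pad) {
  d <- dim(x$val)
  h <- d[1]; w <- d[2]; ci <- d[3]
  H <- (h - 1L) * stride - 2L * pad + kh
  W <- (w - 1L) * stride - 2L * pad + kw
  Xm <- t(matrix(x$val, h * w, ci))
  M <- crossprod(wnode$val, Xm)            # (kh*kw*Co, h*w)
  y <- vs_col2im(M, H, W, co, kh, kw, stride, pad)
  if (!is.null(bnode)) {
    y <- y + rep(bnode$val, each = H * W)
    dim(y) <- c(H, W, co)
  }
  ad_node(y, function(g) {
    dM <- vs_im2col(g, H, W, co, kh, kw, stride, pad)
    ad_acc(wnode, Xm %*% t(dM))
    if (!is.null(bnode)) ad_acc(bnode, colSums(matrix(g, H * W, co)))
    ad_acc(x, array(t(wnode$val %*% dM), c(h, w, ci)))
  })
}

# Depthwise valid cross-correlation with a fixed (non-learnable) 2-D kernel.
ad_dwcorr <- function(x, kernel) {
  d <- dim(x$val)
  y <- vs_dwcorr_valid(x$val, d[1], d[2], d[3], kernel)
  ad_node(y, function(g) ad_acc(x, vs_dwcorr_valid_bw(g, d[1], d[2], d[3], kernel)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
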