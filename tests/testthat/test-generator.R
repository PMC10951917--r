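# Generator architecture contracts: placement codes, sub-module shapes,
# output normalization and gating.

test_that("placement codes instantiate the stated number of attention modules", {
  counts <- c("0000" = 0L, "0001" = 1L, "0011" = 2L, "0111" = 3L, "1111" = 4L)
  for (code in names(counts)) {
    g <- build_generator(generator_config(code, input_slices = 3L, base_channels = 2L))
    expect_identical(n_attention_modules(g), as.integer(counts[[code]]))
  }
  # a 5-level generator exposes exactly 4 attention intervals
  g <- build_generator(generator_config("1111", input_slices = 3L, base_channels = 2L))
  expect_length(g$attn, 4L)
  # "0011" occupies the two intervals nearest the output (largest maps)
  g2 <- build_generator(generator_config("0011", input_slices = 3L, base_channels = 2L))
  expect_true(is.null(g2$attn[[1]]) && is.null(g2$attn[[2]]))
  expect_false(is.null(g2$attn[[3]]) || is.null(g2$attn[[4]]))
  expect_error(generator_config("012"), "placement")
})

test_that("parameter count is non-decreasing in the number of occupied intervals", {
  codes <- c("0000", "0001", "0011", "0111", "1111")
  counts <- vapply(codes, function(code) {
    g <- build_generator(generator_config(code, input_slices = 3L, base_channels = 2L))
    vs$param_count(g$params)
  }, 0)
  expect_true(all(diff(counts) > 0))
})

test_that("mask head has exactly one more channel than the image head", {
  g <- build_generator(generator_config("0000", input_slices = 3L, base_channels = 2L))
  expect_identical(g$head_msk$co, g$head_img$co + 1L)
})

test_that("down/up sub-modules honor their shape contracts and reject bad inputs", {
  blk <- vs$with_seed(1, vs$new_down_block(8L, 16L, sn = FALSE))
  x <- rand_array(c(64, 64, 8))
  vs$ad_begin(FALSE)
  y <- vs$down_fwd(blk, vs$ad_const(x))
  expect_identical(dim(y$val), c(32L, 32L, 16L))
  expect_error(vs$down_fwd(blk, vs$ad_const(rand_array(c(7, 8, 8)))), "even")
  # zero input produces the finite bias response
  z <- vs$down_fwd(blk, vs$ad_const(array(0, c(16, 16, 8))))
  expect_true(all(is.finite(z$val)))
  up <- vs$with_seed(2, vs$new_up_block(32L, 16L, 16L, sn = FALSE))
  yu <- vs$up_fwd(up, vs$ad_const(rand_array(c(16, 16, 32))),
                  vs$ad_const(rand_array(c(32, 32, 16))))
  expect_identical(dim(yu$val), c(32L, 32L, 16L))
  expect_error(vs$up_fwd(up, vs$ad_const(rand_array(c(16, 16, 32))),
                         vs$ad_const(rand_array(c(16, 16, 16)))), "skip")
  # skipless (deepest) variant is a pure up-sampling path
  up0 <- vs$with_seed(3, vs$new_up_block(8L, 0L, 4L, sn = FALSE))
  y0 <- vs$up_fwd(up0, vs$ad_const(rand_array(c(4, 4, 8))), NULL)
  expect_identical(dim(y0$val), c(8L, 8L, 4L))
})

test_that("sub-module forward passes are deterministic under a fixed seed", {
  mk <- function() {
    blk <- vs$with_seed(9, vs$new_down_block(4L, 8L))
    vs$ad_begin(FALSE)
    vs$down_fwd(blk, vs$ad_const(rand_array(c(16, 16, 4))))$val
  }
  expect_identical(mk(), mk())
})

test_that("generate returns bounded images, normalized masks and exact gating", {
  g <- vs$with_seed(5, build_generator(generator_config("0011", input_slices = 4L,
                                                        base_channels = 4L)))
  for (seed in 1:3) {
    x <- vs$with_seed(seed, array(stats::runif(64 * 64 * 4), c(64, 64, 4)))
    out <- generate(g, x)
    expect_identical(dim(out$image), c(64L, 64L, 2L))
    expect_identical(dim(out$mask), c(64L, 64L, 3L))
    expect_true(all(out$image >= -1 & out$image <= 1))
    expect_lt(max(abs(apply(out$mask, c(1, 2), sum) - 1)), 1e-6)
    expect_identical(out$translation, out$image * out$mask[, , 1:2])
  }
  # extreme-valued inputs keep the mask normalized
  xe <- array(rep(c(0, 1), each = 64 * 32 * 4), c(64, 64, 4))
  oute <- generate(g, xe)
  expect_lt(max(abs(apply(oute$mask, c(1, 2), sum) - 1)), 1e-6)
  expect_error(generate(g, array(0.5, c(48, 48, 4))), "divisible")
  expect_error(generate(g, array(0.5, c(64, 64, 3))), "slices")
})

test_that("single-path variants drop the mask decoder and use self-attention", {
  g1 <- build_generator(generator_config("0011", input_slices = 3L,
                                         base_channels = 2L, variant = "single_1ch"))
  expect_null(g1$dec_msk)
  expect_s3_class(g1$attn[[3]], "vs_self_attention")
  expect_identical(g1$head_img$co, 1L)
  g2 <- build_generator(generator_config("0001", input_slices = 3L,
                                         base_channels = 2L, variant = "single_2ch"))
  expect_identical(g2$head_img$co, 2L)
  x <- array(0.5, c(32, 32, 3))
  out <- generate(g2, x)
  expect_null(out$mask)
  expect_identical(out$translation, out$image)
})

test_that("with all gammas zero an occupied placement equals the empty placement", {
  g <- vs$with_seed(6, build_generator(generator_config("0011", input_slices = 3L,
                                                        base_channels = 2L, sn = FALSE)))
  x <- vs$with_seed(7, array(stats::runif(32 * 32 * 3), c(32, 32, 3)))
  out_full <- generate(g, x)
  # strip the attention modules (cross modules at init are exact identities)
  g0 <- g
  g0$attn <- vector("list", 4L)
  out_empty <- generate(g0, x)
  expect_equal(out_full$translation, out_empty$translation, tolerance = 1e-10)
  expect_equal(out_full$mask, out_empty$mask, tolerance = 1e-10)
})
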