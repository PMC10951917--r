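# Detection/classification scoring, slice extraction and file translation.

# build a 3-channel probability mask that predicts a given label/state map
mask_from_labels <- function(lab, states, conf = 0.98) {
  H <- nrow(lab); W <- ncol(lab)
  m <- array((1 - conf) / 2, c(H, W, 3))
  ch <- matrix(3L, H, W)
  for (i in seq_len(max(lab)))
    ch[lab == i] <- if (states[[as.character(i)]] == "healthy") 1L else 2L
  for (c in 1:3) m[, , c][ch == c] <- conf
  m
}

square_instances <- function(n, states, H = 64L) {
  lab <- matrix(0L, H, H)
  k <- 0L
  for (r in seq(4, H - 10, by = 12)) {
    for (cc in seq(4, H - 10, by = 12)) {
      if (k >= n) break
      k <- k + 1L
      lab[r:(r + 6), cc:(cc + 6)] <- k
    }
  }
  stopifnot(k == n)
  vs$new_instances(lab, stats::setNames(states, as.character(seq_len(n))))
}

test_that("a perfect prediction scores accuracy 1 with all error rates 0", {
  truth <- square_instances(5L, c("healthy", "healthy", "apoptotic", "healthy", "apoptotic"))
  rep <- score_detection(mask_from_labels(truth$labels, truth$states), truth)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$false_positive_rate, 0)
  expect_equal(rep$false_negative_rate, 0)
  expect_equal(rep$misclassification_rate, 0)
  expect_identical(rep$n_true, 5L)
  expect_identical(rep$n_detected, 5L)
})

test_that("missed and misclassified nuclei are counted against the right denominators", {
  truth4 <- square_instances(4L, rep("healthy", 4))
  # drop instance 2 from the prediction
  lab_missing <- truth4$labels
  lab_missing[lab_missing == 2L] <- 0L
  pred <- mask_from_labels(lab_missing, truth4$states)
  rep <- score_detection(pred, truth4)
  expect_equal(rep$false_negative_rate, 0.25)
  expect_identical(rep$n_matched, 3L)
  # one healthy nucleus among 10 predicted apoptotic
  truth10 <- square_instances(10L, rep("healthy", 10))
  states_wrong <- truth10$states
  states_wrong["1"] <- "apoptotic"
  rep10 <- score_detection(mask_from_labels(truth10$labels, states_wrong), truth10)
  expect_equal(rep10$h_to_a_rate, 0.1)
  expect_equal(rep10$accuracy, 0.9)
  expect_equal(rep10$misclassification_rate,
               rep10$h_to_a_rate + rep10$a_to_h_rate)
})

test_that("report counts are conserved and invariant to truth label permutation", {
  truth <- square_instances(6L, rep(c("healthy", "apoptotic"), 3))
  lab_missing <- truth$labels
  lab_missing[lab_missing == 5L] <- 0L
  pred <- mask_from_labels(lab_missing, truth$states)
  rep <- score_detection(pred, truth)
  expect_identical(rep$n_matched + rep$n_false_negative, rep$n_true)
  expect_identical(rep$n_matched_pred + rep$n_false_positive, rep$n_detected)
  # permute truth labels
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  lab2 <- truth$labels
  lab2[truth$labels > 0L] <- perm[truth$labels[truth$labels > 0L]]
  st2 <- truth$states[order(perm)]
  names(st2) <- as.character(seq_len(6L))
  truth_p <- vs$new_instances(lab2, st2)
  rep_p <- score_detection(pred, truth_p)
  expect_equal(rep_p$accuracy, rep$accuracy)
  expect_identical(rep_p$n_false_negative, rep$n_false_negative)
})

test_that("empty truth with empty prediction is vacuously perfect", {
  truth <- vs$new_instances(matrix(0L, 16, 16), character(0))
  m <- array(0, c(16, 16, 3)); m[, , 3] <- 1
  rep <- score_detection(m, truth)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$false_negative_rate, 0)
})

test_that("slice extraction keeps the middle layer and the requested geometry", {
  expect_identical(slice_offsets(13L, 1L), 7L)
  # fixed separation: contiguous centered block; 7 slices span 1.8 um
  idx7 <- slice_offsets(13L, 7L, "fixed_separation")
  expect_identical(idx7, 4:10)
  expect_equal((max(idx7) - min(idx7)) * 0.3, 1.8)
  # fixed depth 3.6 um with 3 slices: offsets -6, 0, +6 (1.8 um separation)
  idx3 <- slice_offsets(13L, 3L, "fixed_depth")
  expect_identical(idx3, c(1L, 7L, 13L))
  idx5 <- slice_offsets(13L, 5L, "fixed_depth")
  expect_identical(idx5, c(1L, 4L, 7L, 10L, 13L))
  expect_error(slice_offsets(13L, 4L), "odd")
  expect_error(slice_experiment_spec(slice_counts = c(2, 3)), "odd")
  expect_warning(slice_offsets(13L, 5L, "fixed_depth", depth_um = 3.0), "grid")
})

test_that("translation writes readable fluorescence, mask and report files", {
  g <- vs$with_seed(50, build_generator(generator_config("0000", input_slices = 3L,
                                                         base_channels = 2L, sn = FALSE)))
  sc <- generate_scene(tiny_scene_config(seed = 31L, n_slices = 3L))
  dir <- withr::local_tempdir()
  input <- file.path(dir, "stack.tiff")
  write_stack_tiff(sc$bright_field, input)
  rt <- read_stack_tiff(input)
  expect_identical(dim(rt), dim(sc$bright_field))
  expect_lt(max(abs(rt - sc$bright_field)), 1 / 255)   # 8-bit roundtrip
  out <- translate_files(g, input, file.path(dir, "out"))
  expect_true(all(file.exists(unlist(out))))
  mask <- png::readPNG(out$mask)
  expect_true(all(abs(mask - round(mask * 2) / 2) < 0.01))   # black/gray/white
  rep <- utils::read.delim(out$report)
  expect_true(all(c("label", "state", "area", "centroid_row") %in% names(rep)))
  # identical checkpoint + input produce identical files
  out2 <- translate_files(g, input, file.path(dir, "out2"))
  expect_identical(readBin(out$fluorescence, "raw", 1e6),
                   readBin(out2$fluorescence, "raw", 1e6))
  # checkpoint round trip preserves the translation
  ck <- file.path(dir, "g.rds")
  save_checkpoint(g, ck)
  g2 <- load_checkpoint(ck)
  x <- sc$bright_field
  expect_identical(generate(g2, x)$translation, generate(g, x)$translation)
})

test_that("the slice-count harness trains and evaluates each arm on its sub-stack", {
  ds <- generate_dataset(4L, tiny_scene_config(seed = 905L))
  spec <- slice_experiment_spec(slice_counts = c(1L, 3L), mode = "fixed_depth")
  tab <- slice_experiment(spec, ds,
                          generator_config("0000", input_slices = 13L, base_channels = 4L),
                          discriminator_config(input_slices = 13L, base_channels = 4L),
                          loss_config(),
                          train_config(batch_size = 2L, epochs = 1L,
                                       crop_size = 64L, seed = 9L))
  expect_identical(tab$n_slices, c(1L, 3L))
  expect_true(is.na(tab$separation_um[1]))
  expect_equal(tab$separation_um[2], 1.8)   # 3 slices spanning 3.6 um
  expect_true(all(is.finite(tab$mae)))
  expect_true(all(tab$ssim >= 0 & tab$ssim <= 1))
})
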