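# Nucleus-level detection/classification scoring, slice-count experiment
# harness, and file-level translation.

#' Score nucleus detection and state classification
#'
#' The predicted mask's argmax foreground is split into 8-connected
#' components; each ground-truth instance is matched to the predicted
#' component with maximal overlap, accepted when the overlap covers at least
#' `overlap_threshold` of the truth instance (intersection over truth).
#' Matched nuclei are scored by the majority predicted class over the truth
#' instance; unmatched predictions are false positives (normalized by the
#' number of predicted components), unmatched truths are false negatives
#' (normalized by the number of truth instances, like the accuracy and
#' misclassification rates). Raw counts are returned so any alternative
#' normalization can be recomputed.
#'
#' @param pred_mask (H, W, 3) probability array (healthy, apoptotic,
#'   background)
#' @param truth a `vs_instances` with states set
#' @param overlap_threshold minimum intersection-over-truth fraction
#' @return a `vs_detection_report` list: counts (`n_true`, `n_detected`,
#'   `n_matched`, `n_matched_pred`, `n_false_positive`, `n_false_negative`,
#'   `n_h_to_a`, `n_a_to_h`) and rates (`accuracy`, `false_positive_rate`,
#'   `false_negative_rate`, `misclassification_rate`, `h_to_a_rate`,
#'   `a_to_h_rate`)
#' @export
score_detection <- function(pred_mask, truth, overlap_threshold = 0.3) {
  if (is.null(truth$states)) stop("truth instances must have states set")
  cls <- apply(pred_mask, c(1, 2), which.max)      # 1 healthy, 2 apoptotic, 3 bg
  fg <- cls != 3L
  comps <- matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(fg)))), nrow(fg), ncol(fg))
  n_detected <- max(comps)
  n_true <- max(truth$labels)
  if (n_true == 0L && n_detected == 0L) {
    return(new_detection_report(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, vacuous = TRUE))
  }
  matched_pred <- integer(0)
  n_matched <- 0L
  n_h_to_a <- 0L
  n_a_to_h <- 0L
  for (i in seq_len(n_true)) {
    in_t <- truth$labels == i
    ov <- comps[in_t]
    ov <- ov[ov > 0L]
    if (!length(ov)) next
    tb <- table(ov)
    best <- as.integer(names(tb)[which.max(tb)])
    if (max(tb) / sum(in_t) < overlap_threshold) next
    n_matched <- n_matched + 1L
    matched_pred <- union(matched_pred, best)
    pred_px <- cls[in_t & comps == best]
    pred_state <- if (sum(pred_px == 2L) > sum(pred_px == 1L)) "apoptotic" else "healthy"
    true_state <- truth$states[[as.character(i)]]
    if (true_state == "healthy" && pred_state == "apoptotic") n_h_to_a <- n_h_to_a + 1L
    if (true_state == "apoptotic" && pred_state == "healthy") n_a_to_h <- n_a_to_h + 1L
  }
  new_detection_report(n_true, n_detected, n_matched, length(matched_pred),
                       n_detected - length(matched_pred), n_true - n_matched,
                       n_h_to_a, n_a_to_h)
}

new_detection_report <- function(n_true, n_detected, n_matched, n_matched_pred,
                                 n_fp, n_fn, n_h_to_a, n_a_to_h,
                                 vacuous = FALSE) {
  div <- function(a, b) if (b > 0) a / b else 0
  structure(list(
    n_true = n_true, n_detected = n_detected, n_matched = n_matched,
    n_matched_pred = n_matched_pred, n_false_positive = n_fp,
    n_false_negative = n_fn, n_h_to_a = n_h_to_a, n_a_to_h = n_a_to_h,
    accuracy = if (vacuous) 1 else div(n_matched - n_h_to_a - n_a_to_h, n_true),
    false_positive_rate = div(n_fp, n_detected),
    false_negative_rate = div(n_fn, n_true),
    h_to_a_rate = div(n_h_to_a, n_true),
    a_to_h_rate = div(n_a_to_h, n_true),
    misclassification_rate = div(n_h_to_a + n_a_to_h, n_true)),
    class = "vs_detection_report")
}

#' @export
print.vs_detection_report <- function(x, ...) {
  cat(sprintf(paste0("<vs_detection_report> %d true, %d detected: accuracy %.1f%%, ",
                     "FP %.1f%%, FN %.1f%%, miscls %.1f%% (H>A %.1f%%, A>H %.1f%%)\n"),
              x$n_true, x$n_detected, 100 * x$accuracy,
              100 * x$false_positive_rate, 100 * x$false_negative_rate,
              100 * x$misclassification_rate, 100 * x$h_to_a_rate,
              100 * x$a_to_h_rate))
  invisible(x)
}

#' Slice indices for a sub-stack extraction
#'
#' Centered extraction of `n` slices from an `n_total`-slice stack. With
#' `mode = "fixed_separation"` adjacent selected slices keep the native
#' spacing (contiguous centered block); with `mode = "fixed_depth"` the
#' selected slices span `depth_um` (separation grows as the slice count
#' shrinks). Non-representable separations round to the nearest slice with a
#' warning. Only odd `n` keeps the middle slice, so even counts are
#' rejected.
#'
#' @param n_total total slices available
#' @param n slices to extract (odd)
#' @param mode "fixed_separation" or "fixed_depth"
#' @param spacing_um native slice spacing
#' @param depth_um stack depth to span in fixed_depth mode
#' @return integer vector of slice indices
#' @export
slice_offsets <- function(n_total = 13L, n, mode = c("fixed_separation", "fixed_depth"),
                          spacing_um = 0.3, depth_um = 3.6) {
  mode <- match.arg(mode)
  if (n %% 2L == 0L) stop("odd slice counts only (keeps the same middle layer)")
  ctr <- (n_total + 1L) %/% 2L
  if (n == 1L) return(ctr)
  half <- (n - 1L) %/% 2L
  if (mode == "fixed_separation") {
    step <- 1L
  } else {
    sep_um <- depth_um / (n - 1L)
    step_f <- sep_um / spacing_um
    step <- max(1L, as.integer(round(step_f)))
    if (abs(step_f - step) > 1e-9)
      warning(sprintf("separation %.3g um not on the %.3g um grid; using %d-slice steps",
                      sep_um, spacing_um, step))
  }
  idx <- ctr + step * (-half:half)
  if (any(idx < 1L | idx > n_total))
    stop("requested sub-stack exceeds the source stack")
  idx
}

#' Slice-count experiment specification
#'
#' @param slice_counts odd slice counts to test
#' @param mode "fixed_separation" (keep native spacing) or "fixed_depth"
#'   (keep total stack depth)
#' @param spacing_um native spacing
#' @param depth_um fixed depth for fixed_depth mode
#' @return a `vs_slice_spec` list
#' @export
slice_experiment_spec <- function(slice_counts = c(1L, 3L, 5L, 7L),
                                  mode = c("fixed_separation", "fixed_depth"),
                                  spacing_um = 0.3, depth_um = 3.6) {
  mode <- match.arg(mode)
  if (any(slice_counts %% 2L == 0L)) stop("odd slice counts only")
  structure(list(slice_counts = as.integer(slice_counts), mode = mode,
                 spacing_um = spacing_um, depth_um = depth_um),
            class = "vs_slice_spec")
}

subset_dataset_slices <- function(dataset, idx) {
  out <- dataset
  out$scenes <- lapply(dataset$scenes, function(sc) {
    sc$bright_field <- sc$bright_field[, , idx, drop = FALSE]
    sc$config$n_slices <- length(idx)
    sc
  })
  out
}

#' Run the slice-count experiment
#'
#' For each requested slice count, extracts the centered sub-stack, trains
#' an identically configured model, and evaluates MAE/SSIM/PSNR on the test
#' fold.
#'
#' @param spec a [slice_experiment_spec()]
#' @param dataset a `vs_dataset`
#' @param g_config,d_config,l_config,t_config model and training configs;
#'   `input_slices` is overridden per arm
#' @return data frame with one row per arm
#' @export
slice_experiment <- function(spec, dataset, g_config, d_config,
                             l_config = loss_config(), t_config = train_config()) {
  n_total <- dim(dataset$scenes[[1]]$bright_field)[3]
  rows <- lapply(spec$slice_counts, function(n) {
    idx <- slice_offsets(n_total, n, spec$mode, spec$spacing_um, spec$depth_um)
    ds <- subset_dataset_slices(dataset, idx)
    gc <- g_config; gc$input_slices <- length(idx)
    dc <- d_config; dc$input_slices <- length(idx)
    fit <- use_best_checkpoint(train(ds, gc, dc, l_config, t_config))
    ev <- evaluate_fit(fit, ds, split = "test")
    data.frame(n_slices = n, mode = spec$mode,
               separation_um = if (n == 1L) NA_real_ else (idx[2] - idx[1]) * spec$spacing_um,
               mae = ev$mae, ssim = ev$ssim, psnr = ev$psnr,
               detection_accuracy = ev$detection_accuracy)
  })
  do.call(rbind, rows)
}

#' Evaluate a fit on a dataset split
#'
#' @param fit a `vs_fit`
#' @param dataset the dataset the fit was trained on
#' @param split which fold to evaluate ("test", "val" or "train")
#' @return list with mean `mae`, `ssim`, `psnr`, `detection_accuracy` and
#'   the per-scene `reports`
#' @export
evaluate_fit <- function(fit, dataset, split = "test") {
  idx <- which(dataset$split == split)
  if (!length(idx)) stop("no scenes in split ", split)
  acc <- c(mae = 0, ssim = 0, psnr = 0)
  reports <- list()
  dual <- fit$g_config$variant == "dual"
  for (i in idx) {
    sc <- dataset$scenes[[i]]
    out <- generate(fit$generator, sc$bright_field, sn_iter = fit$t_config$sn_iter)
    tgt <- sc$fluorescent_target
    if (fit$g_config$variant == "single_1ch") {
      t1 <- pmax(tgt[, , 1], tgt[, , 2])
      tgt <- array(t1, c(dim(t1), 1L))
    }
    pred <- pmin(pmax(out$translation, 0), 1)
    mt <- metrics(pred, tgt, dynamic_range = 1)
    acc <- acc + c(mt$mae, mt$ssim, min(mt$psnr, 99))
    if (dual) reports[[length(reports) + 1L]] <- score_detection(out$mask, sc$instances)
  }
  acc <- acc / length(idx)
  list(mae = unname(acc["mae"]), ssim = unname(acc["ssim"]),
       psnr = unname(acc["psnr"]),
       detection_accuracy = if (length(reports))
         mean(vapply(reports, function(r) r$accuracy, 0)) else NA_real_,
       reports = reports)
}

# ---- file-level translation ----------------------------------------------

#' Read a multi-page TIFF as an (H, W, S) array
#' @param path TIFF path
#' @return numeric array
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}

#' Write an (H, W, S) array as a multi-page TIFF
#' @param arr numeric array with values in \[0, 1\]
#' @param path output path
#' @export
write_stack_tiff <- function(arr, path) {
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  pages <- lapply(seq_len(dim(arr)[3]), function(s) pmin(pmax(arr[, , s], 0), 1))
  tiff::writeTIFF(pages, path)
  invisible(path)
}

#' Save / load a generator checkpoint
#'
#' Serializes the generator configuration and parameter values.
#'
#' @param g a `vs_generator`
#' @param path checkpoint path (.rds)
#' @export
save_checkpoint <- function(g, path) {
  saveRDS(list(config = g$config, params = snapshot_params(g$params)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the reconstructed `vs_generator`
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  g <- build_generator(ck$config)
  restore_params(g$params, ck$params)
  g
}

#' Translate a bright-field stack file and write the outputs
#'
#' Writes the 2-channel fluorescent translation (multi-page TIFF), the class
#' mask as a PNG (gray = healthy, white = apoptotic, black = background) and
#' a per-nucleus state report (tab-delimited: label, state, area, centroid).
#'
#' @param g a `vs_generator` or a checkpoint path
#' @param input_stack_path multi-page TIFF of the bright-field stack
#' @param output_dir output directory (created if needed)
#' @return named list of written paths
#' @export
translate_files <- function(g, input_stack_path, output_dir) {
  if (is.character(g)) g <- load_checkpoint(g)
  x <- read_stack_tiff(input_stack_path)
  if (dim(x)[3] != g$config$input_slices)
    stop(sprintf("input has %d slices but the checkpoint expects S = %d",
                 dim(x)[3], g$config$input_slices))
  rng <- range(x)
  if (rng[2] > rng[1]) x <- (x - rng[1]) / (rng[2] - rng[1])
  out <- generate(g, x)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  base <- sub("\\.tiff?$", "", basename(input_stack_path), ignore.case = TRUE)
  p_fluo <- file.path(output_dir, paste0(base, "_fluorescence.tiff"))
  write_stack_tiff(pmin(pmax(out$translation, 0), 1), p_fluo)
  cls <- apply(out$mask, c(1, 2), which.max)
  mask_img <- matrix(0, nrow(cls), ncol(cls))
  mask_img[cls == 1L] <- 0.5   # gray: healthy
  mask_img[cls == 2L] <- 1     # white: apoptotic
  p_mask <- file.path(output_dir, paste0(base, "_mask.png"))
  png::writePNG(mask_img, p_mask)
  fg <- cls != 3L
  comps <- matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(fg)))), nrow(fg), ncol(fg))
  rows <- lapply(seq_len(max(comps, 0L)), function(i) {
    px <- which(comps == i, arr.ind = TRUE)
    st <- if (sum(cls[px] == 2L) > sum(cls[px] == 1L)) "apoptotic" else "healthy"
    data.frame(label = i, state = st, area = nrow(px),
               centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]))
  })
  report <- if (length(rows)) do.call(rbind, rows)
    else data.frame(label = integer(0), state = character(0), area = integer(0),
                    centroid_row = numeric(0), centroid_col = numeric(0))
  p_rep <- file.path(output_dir, paste0(base, "_nuclei.tsv"))
  utils::write.table(report, p_rep, sep = "\t", row.names = FALSE, quote = FALSE)
  list(fluorescence = p_fluo, mask = p_mask, report = p_rep)
}
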