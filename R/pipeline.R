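default_config <- function() {
  list(
    seed = 1,
    backend = "exact",
    data = list(n_phantoms = 40, size = 32, split_ratio = 0.8, lesion_area_frac = 0.08,
                speckle_scale = 0.3, gaussian_sigma = 0.02, contrast = 0.3,
                benign_frac = 0.5),
    denoiser = list(depth = 5, width = 12, epochs = 40, learning_rate = 5e-3,
                    batch_size = 8),
    optimizer = list(enabled = FALSE, pop = 4, iters = 2, budget_epochs = 15,
                     val_frac = 0.25),
    segmenter = list(depth = 5, width = 16, epochs = 60, learning_rate = 5e-3,
                     batch_size = 8, threshold = 0.5, radius = 1)
  )
}

check_schema <- function(cfg, ref = default_config(), path = "") {
  for (k in names(cfg)) {
    if (!k %in% names(ref))
      stop("unknown configuration key: ", path, k)
    if (is.list(ref[[k]]) && !is.null(cfg[[k]]))
      check_schema(cfg[[k]], ref[[k]], paste0(path, k, "."))
  }
  invisible(TRUE)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration (or takes a list), validates it against the
#' known schema (unknown keys are rejected), and fills unset values with
#' the defaults.
#'
#' @param x path to a YAML file, a list, or `NULL` for pure defaults.
#' @return A validated `run_config` list.
#' @export
run_config <- function(x = NULL) {
  cfg <- default_config()
  if (is.character(x)) x <- yaml::read_yaml(x)
  if (!is.null(x)) {
    stopifnot(is.list(x))
    check_schema(x)
    cfg <- modifyList(cfg, x)
  }
  stopifnot(cfg$backend %in% c("exact", "cutin_fp32", "cutin_fp16"))
  structure(cfg, class = "run_config")
}

# stable 64-bit-ish FNV-1a content hash of the configuration
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full phantom segmentation pipeline
#'
#' Executes the complete workflow: phantom generation, denoiser training,
#' denoising, optional POA hyperparameter tuning, segmenter training,
#' segmentation with morphological post-processing, lesion classification,
#' and evaluation. All randomness is governed by the single configuration
#' seed, so a fixed configuration reproduces the report bit-identically.
#' Stage progress is logged to the message stream; the report contains no
#' timestamps.
#'
#' @param cfg a [run_config()].
#' @param out_json optional path; when set, the report is also written as
#'   pretty-printed JSON.
#' @return The report: configuration echo + hash, per-stage results
#'   (denoising PSNR/SSIM, segmentation scores, classification accuracy
#'   and lesion-level confusion counts, POA trace if enabled).
#' @export
run_pipeline <- function(cfg = run_config(), out_json = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- proc.time()[3]

  log_stage("gen-data", sprintf("generating %d phantoms (%dx%d)",
                                cfg$data$n_phantoms, cfg$data$size, cfg$data$size))
  ds <- generate_dataset(
    n = cfg$data$n_phantoms,
    class_mix = c(benign = cfg$data$benign_frac,
                  malignant = 1 - cfg$data$benign_frac),
    split_ratio = cfg$data$split_ratio, seed = cfg$seed,
    size = cfg$data$size, lesion_area_frac = cfg$data$lesion_area_frac,
    speckle_scale = cfg$data$speckle_scale,
    gaussian_sigma = cfg$data$gaussian_sigma, contrast = cfg$data$contrast)

  log_stage("train-denoiser", sprintf("depth %d width %d, %d epochs",
                                      cfg$denoiser$depth, cfg$denoiser$width,
                                      cfg$denoiser$epochs))
  dn <- dncnn_build(network_spec(depth = cfg$denoiser$depth,
                                 width = cfg$denoiser$width,
                                 head = "denoise"))
  dn <- dncnn_train(dn,
                    lapply(ds$train, `[[`, "noisy"),
                    lapply(ds$train, `[[`, "image"),
                    train_config(learning_rate = cfg$denoiser$learning_rate,
                                 epochs = cfg$denoiser$epochs,
                                 batch_size = cfg$denoiser$batch_size,
                                 seed = cfg$seed + 1))

  log_stage("denoise", sprintf("backend %s", cfg$backend))
  den_train <- lapply(ds$train, function(p) dncnn_denoise(dn, p$noisy, cfg$backend))
  den_test <- lapply(ds$test, function(p) dncnn_denoise(dn, p$noisy, cfg$backend))
  psnr_noisy <- vapply(ds$test, function(p) psnr(p$image, p$noisy), numeric(1))
  psnr_den <- mapply(function(p, d) psnr(p$image, d), ds$test, den_test)
  ssim_den <- mapply(function(p, d) ssim(p$image, d), ds$test, den_test)

  hp_pos <- hyper_default()
  hp_pos[2] <- cfg$segmenter$depth
  hp_pos[3] <- cfg$segmenter$width
  hp_pos[1] <- log10(cfg$segmenter$learning_rate)
  hp_pos[4] <- cfg$segmenter$threshold
  hp_pos[5] <- cfg$segmenter$radius
  poa_trace <- NULL
  if (isTRUE(cfg$optimizer$enabled)) {
    log_stage("optimize", sprintf("POA N=%d T=%d", cfg$optimizer$pop,
                                  cfg$optimizer$iters))
    nval <- max(2, round(length(ds$train) * cfg$optimizer$val_frac))
    sub_val <- ds$train[seq_len(nval)]
    sub_train <- ds$train[-seq_len(nval)]
    sub_train_den <- mapply(function(p, d) { p$noisy <- d; p },
                            sub_train, den_train[-seq_len(nval)],
                            SIMPLIFY = FALSE)
    sub_val_den <- mapply(function(p, d) { p$noisy <- d; p },
                          sub_val, den_train[seq_len(nval)], SIMPLIFY = FALSE)
    fit_fn <- function(pos) dncnn_fitness(pos, sub_train_den, sub_val_den,
                                          budget_epochs = cfg$optimizer$budget_epochs,
                                          seed = cfg$seed + 2)
    res <- poa_optimize(fit_fn, hyper_bounds(),
                        poa_config(N = cfg$optimizer$pop,
                                   T = cfg$optimizer$iters,
                                   seed = cfg$seed + 3),
                        warm_start = hp_pos)
    poa_trace <- res$trace
    # deploy the better of tuned and incumbent at the full training budget,
    # judged on the validation phantoms only
    log_stage("train-segmenter",
              sprintf("full-budget selection over 2 candidates, %d epochs",
                      cfg$segmenter$epochs))
    sel <- select_segmenter(list(decode_hyper(res$best$position),
                                 decode_hyper(hp_pos)),
                            den_train, lapply(ds$train, `[[`, "mask"),
                            val_idx = seq_len(nval),
                            epochs = cfg$segmenter$epochs,
                            batch_size = cfg$segmenter$batch_size,
                            seed = cfg$seed + 4)
    sg <- sel$net
    hp <- sel$hp
  } else {
    hp <- decode_hyper(hp_pos)
    log_stage("train-segmenter", sprintf("depth %d width %d, %d epochs",
                                         hp$depth, hp$width,
                                         cfg$segmenter$epochs))
    sg <- dncnn_build(network_spec(depth = hp$depth, width = hp$width,
                                   head = "segment"))
    sg <- dncnn_train(sg, den_train, lapply(ds$train, `[[`, "mask"),
                      train_config(learning_rate = hp$learning_rate,
                                   epochs = cfg$segmenter$epochs,
                                   batch_size = cfg$segmenter$batch_size,
                                   seed = cfg$seed + 4,
                                   mask_threshold = hp$threshold))
  }

  log_stage("segment", "predicting and post-processing test masks")
  pred_masks <- lapply(den_test, function(d) {
    m <- dncnn_segment(sg, d, threshold = hp$threshold, backend = cfg$backend)
    postprocess_mask(m, hp$radius)
  })

  log_stage("classify", "P-SVM on shape/texture/intensity features")
  # features come from the same segmentation pipeline on both sides:
  # predicted masks, with the ground-truth mask as fallback when empty
  pred_train <- lapply(den_train, function(d) {
    m <- dncnn_segment(sg, d, threshold = hp$threshold, backend = cfg$backend)
    postprocess_mask(m, hp$radius)
  })
  feat_of <- function(img, mk, fallback)
    extract_features(img, if (any(mk == 1)) mk else fallback)
  tr_feat <- lapply(seq_along(ds$train), function(i)
    feat_of(den_train[[i]], pred_train[[i]], ds$train[[i]]$mask))
  tr_lab <- vapply(ds$train, `[[`, "", "label")
  model <- psvm_fit(tr_feat, tr_lab)
  te_lab <- vapply(ds$test, `[[`, "", "label")
  te_pred <- vapply(seq_along(ds$test), function(i) {
    as.integer(psvm_predict(model, feat_of(den_test[[i]], pred_masks[[i]],
                                           ds$test[[i]]$mask)))
  }, integer(1))
  te_truth <- as.integer(te_lab == "malignant")
  cls_cm <- confusion_counts(TP = sum(te_pred == 1 & te_truth == 1, na.rm = TRUE),
                             TN = sum(te_pred == 0 & te_truth == 0, na.rm = TRUE),
                             FP = sum(te_pred == 1 & te_truth == 0, na.rm = TRUE),
                             FN = sum(te_pred == 0 & te_truth == 1, na.rm = TRUE))

  log_stage("evaluate", "segmentation and image-quality metrics")
  seg_eval <- evaluate_masks(pred_masks, lapply(ds$test, `[[`, "mask"))

  report <- list(
    config = unclass(cfg),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    n_train = length(ds$train), n_test = length(ds$test),
    denoising = list(psnr_noisy_db = mean(psnr_noisy),
                     psnr_denoised_db = mean(psnr_den),
                     psnr_gain_db = mean(psnr_den) - mean(psnr_noisy),
                     ssim_denoised = mean(ssim_den)),
    hyperparameters = hp,
    poa_trace = poa_trace,
    segmentation = as.list(seg_eval$mean),
    classification = list(accuracy = mean(te_pred == te_truth, na.rm = TRUE),
                          confusion = unclass(cls_cm),
                          misclassified = sum(te_pred != te_truth, na.rm = TRUE))
  )
  log_stage("done", sprintf("%.1f s elapsed", proc.time()[3] - t0))
  if (!is.null(out_json)) {
    dir.create(dirname(out_json), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(report)
}
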